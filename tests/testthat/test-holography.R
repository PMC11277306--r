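test_that("spot rasterization matches the field geometry", {
  t1 <- make_target(list(list(center_um = c(100, 0), width_um = 50,
                              height_um = 250)), c(256, 256), 5)
  expect_equal(sum(t1 > 0), 10 * 50)
  ext <- apply(which(t1 > 0, arr.ind = TRUE), 2, range)
  expect_equal(diff(ext[, "col"]) + 1, 10)
  expect_equal(diff(ext[, "row"]) + 1, 50)

  # two disjoint spots: pixel counts add
  t2 <- make_target(list(
    list(center_um = c(-150, -150), width_um = 50, height_um = 100),
    list(center_um = c(150, 150), width_um = 80, height_um = 40)),
    c(256, 256), 5)
  expect_equal(sum(t2 > 0), 10 * 20 + 16 * 8)
  expect_identical(sort(unique(as.vector(t2))), c(0L, 1L, 2L))

  # 90-degree rotation transposes the footprint
  tr <- make_target(list(list(center_um = c(0, 0), width_um = 50,
                              height_um = 250, angle_deg = 90)),
                    c(256, 256), 5)
  extr <- apply(which(tr > 0, arr.ind = TRUE), 2, range)
  expect_equal(diff(extr[, "col"]) + 1, 50)
  expect_equal(diff(extr[, "row"]) + 1, 10)

  expect_error(make_target(list(list(center_um = c(700, 0), width_um = 50,
                                     height_um = 50)), c(256, 256), 5),
               "outside")
})

test_that("reconstruction conserves power and the block removes the DC spot", {
  # uniform (zero) phase: all power at the centre pixel
  I0 <- reconstruct(matrix(0, 64, 64))
  expect_equal(sum(I0), 1, tolerance = 1e-9)
  expect_equal(I0[33, 33], 1, tolerance = 1e-9)
  Ib <- reconstruct(matrix(0, 64, 64), block_radius_px = 3)
  expect_equal(Ib[33, 33], 0)

  set.seed(60)
  ph <- matrix(runif(64 * 64, 0, 2 * pi), 64, 64)
  expect_equal(sum(reconstruct(ph)), 1, tolerance = 1e-9)
})

test_that("GSW concentrates power on a single off-centre spot", {
  tgt <- matrix(0L, 128, 128)
  tgt[80, 90] <- 1L
  hp <- gsw_phase(tgt, n_iter = 30, seed = 2)
  am <- which(hp$intensity == max(hp$intensity), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(80L, 90L))
  expect_gt(hp$efficiency, 0.5)
  # converged phase of a single off-centre spot is a linear ramp mod 2pi:
  # the wrapped column-difference is constant
  dcol <- diff(hp$phase[64, ]) %% (2 * pi)
  expect_lt(sd(pmin(dcol, 2 * pi - dcol)), 0.05)
  expect_error(gsw_phase(matrix(0L, 16, 16)), "empty")
})

test_that("iterating GSW improves multi-spot efficiency and uniformity", {
  tgt <- make_target(list(
    list(center_um = c(-150, -100), width_um = 40, height_um = 40),
    list(center_um = c(150, 0), width_um = 40, height_um = 40),
    list(center_um = c(0, 150), width_um = 40, height_um = 40)),
    c(128, 128), 5)
  h1 <- gsw_phase(tgt, n_iter = 1, seed = 4)
  h30 <- gsw_phase(tgt, n_iter = 30, seed = 4)
  expect_gte(h30$uniformity, h1$uniformity)
  expect_gte(h30$efficiency, h1$efficiency - 0.01)
  expect_true(all(h30$phase >= 0 & h30$phase < 2 * pi))
})

test_that("translating the target translates the reconstruction", {
  tgt <- matrix(0L, 64, 64)
  tgt[30, 30] <- 1L
  sh <- matrix(0L, 64, 64)
  sh[36, 30] <- 1L
  a <- gsw_phase(tgt, n_iter = 20, seed = 5)$intensity
  b <- gsw_phase(sh, n_iter = 20, seed = 5)$intensity
  am <- which(a == max(a), arr.ind = TRUE)
  bm <- which(b == max(b), arr.ind = TRUE)
  expect_equal(unname(bm[1, ] - am[1, ]), c(6L, 0L))
})
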