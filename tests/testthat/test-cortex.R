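test_that("ischemia classes follow the printed thresholds", {
  rel <- matrix(c(0.85, 0.5, 0.3, 0.15), 2, 2)
  lab <- classify_ischemia(rel, matrix(TRUE, 2, 2))
  expect_identical(as.vector(lab$labels),
                   c("normal", "benign", "penumbra", "infarct"))
  # boundaries: half-open, the stated lower bound belongs to the class
  b <- classify_ischemia(matrix(c(0.8, 0.4, 0.2, 1), 2, 2),
                         matrix(TRUE, 2, 2))
  expect_identical(as.vector(b$labels),
                   c("normal", "benign", "penumbra", "normal"))
  expect_error(classify_ischemia(rel, matrix(FALSE, 2, 2)), "empty")
  expect_error(classify_ischemia(matrix(-0.1, 2, 2), matrix(TRUE, 2, 2)),
               "non-negative")
})

test_that("class fractions count pixels and partition the mask", {
  rel <- matrix(1, 10, 10)
  rel[1:3, 1:10] <- 0.3
  lab <- classify_ischemia(rel, matrix(TRUE, 10, 10))
  expect_equal(unname(lab$fractions["penumbra"]), 0.30)
  expect_equal(sum(lab$fractions), 1, tolerance = 1e-9)

  set.seed(50)
  arr <- array(runif(12 * 12 * 6, 0, 1.4), dim = c(12, 12, 6))
  mask <- matrix(runif(144) > 0.3, 12, 12)
  fr <- area_fraction_series(arr, mask)
  expect_true(all(abs(rowSums(fr[, -1]) - 1) < 1e-9))
  # all-normal frames give zero ischemic fractions
  fr0 <- area_fraction_series(array(1, dim = c(8, 8, 3)),
                              matrix(TRUE, 8, 8))
  expect_true(all(fr0$benign == 0 & fr0$penumbra == 0 & fr0$infarct == 0))
})

test_that("deepening the flow deficit never shrinks the ischemic area", {
  sev <- matrix(seq(0.05, 0.9, length.out = 100), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  isch <- vapply(seq(0, 1, 0.1), function(deficit) {
    lab <- classify_ischemia(1 - sev * deficit, mask)
    sum(lab$fractions[c("benign", "penumbra", "infarct")])
  }, numeric(1))
  expect_true(all(diff(isch) >= 0))
})

test_that("a constructed travelling trough is one ordered SD event", {
  tt <- seq(0, 60, 0.2)
  mk <- function(t0) data.frame(
    time_s = tt, value = 1 - 0.4 * exp(-(tt - t0)^2 / (2 * 2^2)))
  traces <- lapply(c(10, 20, 30, 40), mk)
  ev <- detect_sd(traces, spacing_um = 250)
  expect_equal(ev$count, 1L)
  expect_identical(ev$events[[1]]$roi, 1:4)
  expect_true(all(diff(ev$events[[1]]$time_s) > 0))
  expect_equal(ev$speed_um_s, 25, tolerance = 0.05 * 25)

  flat <- lapply(1:4, function(i) data.frame(time_s = tt, value = rep(1, length(tt))))
  expect_equal(detect_sd(flat)$count, 0L)
  expect_error(detect_sd(flat[1:2]), "3 ROIs")
})

test_that("the simulated SD wave is recovered with the configured speed", {
  res <- sd_run()
  expect_equal(res$sd$count, 1L)
  v_true <- res$cfg$sd$speed_mm_min * 1000 / 60
  expect_lt(abs(res$sd$speed_um_s - v_true) / v_true, 0.10)
})

test_that("correlation maps match cor() and flag degenerate pixels", {
  set.seed(51)
  ref <- rnorm(60)
  arr <- array(rnorm(6 * 6 * 60), dim = c(6, 6, 60))
  arr[1, 1, ] <- ref                      # self-correlation
  arr[2, 1, ] <- -ref                     # anti-correlation
  arr[3, 1, ] <- 5                        # zero variance
  cm <- correlation_map(ref, arr, matrix(TRUE, 6, 6))
  expect_equal(cm$r[1, 1], 1)
  expect_equal(cm$r[2, 1], -1)
  expect_true(is.na(cm$r[3, 1]))
  expect_equal(cm$n_undefined, 1L)
  for (i in 4:6) for (j in 1:6)
    expect_equal(cm$r[i, j], cor(ref, arr[i, j, ]), tolerance = 1e-10)
  expect_true(all(abs(cm$r) <= 1, na.rm = TRUE))
})

test_that("designed regional correlations are recovered", {
  set.seed(52)
  ref <- rnorm(300)
  r_target <- matrix(rep(c(0.2, 0.8), each = 72), 12, 12)
  arr <- make_correlated_stack(ref, r_target, seed = 53)
  cm <- correlation_map(ref, arr, matrix(TRUE, 12, 12))
  lo <- r_target == 0.2
  expect_lt(abs(mean(cm$r[lo]) - 0.2), 0.05)
  expect_lt(abs(mean(cm$r[!lo]) - 0.8), 0.05)
})

test_that("max benign area during occlusion matches the designed severity", {
  # SD-free episode so the steady ischemic field is not masked by the wave
  cfg <- synth_config(seed = 44, frame_size = c(64, 64), um_per_pixel = 5,
                      rate_schedule = list(c(0, 2)), duration_s = 300,
                      baseline_duration_s = 25,
                      sd = list(amplitude = 0),
                      kinetics = list(k_off = 2e-3, persist_tau_s = 30))
  mv <- generate_flow_movie(cfg)
  stack <- render_speckle(mv$flow, cfg)
  bfi <- contrast_to_bfi(compute_contrast(stack))
  rel <- relative_bfi_series(bfi, c(0.5, 24))
  fr <- area_fraction_series(rel, mv$truth$region_masks$cortex)
  ev <- mv$truth$events
  occ <- fr$time_s > ev$occlusion_onset + 5 & fr$time_s < ev$occlusion_end - 5
  got <- median(fr$benign[occ])
  expect_lt(abs(got - mv$truth$design_fractions["benign"]), 0.05)
})
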