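# Frames for constructed streams: a vertical vessel on parenchyma, rendered
# with the same gamma speckle encoding the simulator uses.
make_ctrl_frame <- function(vessel_rel, cfg, geo, seed) {
  set.seed(seed)
  fr <- matrix(1, geo$nr, geo$nc)
  fr[, geo$base_cols] <- cfg$vessel$flow_gain * vessel_rel
  n_avg <- round(1 + cfg$speckle$g * fr)
  matrix(cfg$speckle$mean_counts *
           stats::rgamma(length(n_avg), n_avg, n_avg), geo$nr, geo$nc)
}

test_that("the controller stops k frames after a constructed crossing", {
  cfg <- synth_config(seed = 1, frame_size = c(64, 48))
  geo <- synth_geometry(cfg)
  ctrl <- controller_init(geo$light_spot_roi, cfg$um_per_pixel, k = 5L)
  expect_error(controller_step(ctrl, make_ctrl_frame(1, cfg, geo, 1), 0),
               "baseline")
  base_frames <- lapply(1:10, function(i) make_ctrl_frame(1, cfg, geo, i))
  ctrl <- controller_baseline(ctrl, base_frames)

  t <- 0
  for (i in 1:20) {             # healthy flow: keep_on
    res <- controller_step(ctrl, make_ctrl_frame(1, cfg, geo, 100 + i), t)
    ctrl <- res$state; t <- t + 0.1
  }
  expect_identical(res$command, "keep_on")
  expect_equal(ctrl$consecutive_below, 0L)
  n_below <- 0L
  while (!ctrl$stopped) {       # occluded: BF collapses below threshold
    n_below <- n_below + 1L
    res <- controller_step(ctrl, make_ctrl_frame(0.02, cfg, geo, 200 + n_below), t)
    ctrl <- res$state; t <- t + 0.1
  }
  expect_identical(res$command, "stop")
  expect_equal(n_below, 5L)     # exactly k consecutive sub-threshold frames
  expect_false(ctrl$timeout)
  # illumination is never re-enabled after the stop
  res2 <- controller_step(ctrl, make_ctrl_frame(1, cfg, geo, 999), t)
  expect_identical(res2$command, "stop")
  expect_false(res2$state$illumination_on)
})

test_that("a stream that never occludes stops on timeout with the flag", {
  cfg <- synth_config(seed = 2, frame_size = c(64, 48))
  geo <- synth_geometry(cfg)
  ctrl <- controller_init(geo$light_spot_roi, cfg$um_per_pixel,
                          max_duration_s = 3)
  ctrl <- controller_baseline(ctrl, lapply(1:5, function(i)
    make_ctrl_frame(1, cfg, geo, i)))
  t <- 0; res <- NULL
  repeat {
    res <- controller_step(ctrl, make_ctrl_frame(1, cfg, geo, 50 + t * 10), t)
    ctrl <- res$state
    if (ctrl$stopped) break
    t <- t + 0.5
  }
  expect_true(ctrl$timeout)
  expect_gte(ctrl$stop_time - ctrl$light_onset_s, 3)
})

test_that("closed-loop runs are reproducible and sensitive to forcing", {
  a <- run_closed_loop(loop_cfg(5L))
  b <- run_closed_loop(loop_cfg(5L))
  expect_equal(a$report$d_s, b$report$d_s, tolerance = 1e-9)
  expect_equal(a$truth$traces$theta, b$truth$traces$theta, tolerance = 1e-12)

  # no light at all: no occlusion, timeout
  cfg0 <- loop_cfg(5L)
  cfg0$light$intensity <- 0
  cfg0$kinetics$k_on <- 0
  cfg0$light$max_duration_s <- 200
  r0 <- run_closed_loop(cfg0)
  expect_true(is.na(r0$report$occlusion_onset))
  expect_true(r0$report$timeout)
})

test_that("faster thrombosis shortens the realized time to occlusion", {
  slow <- loop_cfg(6L)
  fast <- loop_cfg(6L)
  fast$kinetics$k_on <- fast$kinetics$k_on * 4
  fast$kinetics$k_auto <- fast$kinetics$k_auto * 1.5
  r_slow <- run_closed_loop(slow)$report
  r_fast <- run_closed_loop(fast)$report
  expect_lt(r_fast$c_s, r_slow$c_s)
})

test_that("stopping earlier never lengthens the realized occlusion", {
  ds <- vapply(c(3L, 5L, 15L), function(k) {
    run_closed_loop(loop_cfg(7L), controller_params = list(k = k))$report$d_s
  }, numeric(1))
  expect_true(all(is.finite(ds)))
  expect_lte(ds[1], ds[2] + 1.5)
  expect_lte(ds[2], ds[3] + 1.5)
})
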