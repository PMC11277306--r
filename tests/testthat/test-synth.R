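test_that("configuration validation rejects bad schedules and rates", {
  expect_error(synth_config(rate_schedule = list(c(5, 10))), "t = 0")
  expect_error(synth_config(rate_schedule = list(c(0, -1))), "positive")
  expect_error(synth_config(kinetics = list(k_on = -1)), "non-negative")
  expect_error(synth_config(kinetics = list(bogus = 1)), "unknown keys")
  expect_error(synth_config(duration_s = 10), "exceed")
})

test_that("schedule timestamps follow the acquisition-rate changes", {
  ts <- schedule_timestamps(list(c(0, 10), c(2, 2)), 4)
  expect_equal(ts[1:3], c(0, 0.1, 0.2))
  expect_true(all(abs(diff(ts[ts >= 2.01]) - 0.5) < 1e-9))
  expect_true(all(diff(ts) > 0))
})

test_that("no light forcing leaves the vessel untouched", {
  cfg <- synth_config(seed = 3, frame_size = c(48, 48), duration_s = 60,
                      baseline_duration_s = 10,
                      rate_schedule = list(c(0, 2)),
                      kinetics = list(k_on = 0, jitter_sd = 0))
  mv <- generate_flow_movie(cfg)
  tr <- mv$truth$traces
  expect_true(all(tr$theta == 0))
  expect_true(all(tr$w_px == tr$w_px[1]))
  expect_true(all(abs(tr$bf_rel - 1) < 1e-12))
  expect_true(is.na(mv$truth$events$occlusion_onset))
  expect_identical(mv$truth$events$status, "no_occlusion")
})

test_that("without lysis the occupancy grows monotonically to saturation", {
  cfg <- synth_config(seed = 3, frame_size = c(48, 48), duration_s = 400,
                      baseline_duration_s = 10,
                      rate_schedule = list(c(0, 2)),
                      light = list(mode = "fixed", duration_s = 380),
                      kinetics = list(k_off = 0, jitter_sd = 0))
  mv <- generate_flow_movie(cfg)
  th <- mv$truth$traces$theta
  expect_true(all(diff(th) > -1e-12))
  expect_gt(max(th), 0.99)
  expect_true(all(diff(mv$truth$traces$w_px) <= 0L))
})

test_that("identical seeds reproduce bit-identical runs, seeds differ in noise", {
  cfg <- small_cfg(7L)
  a <- generate_flow_movie(cfg)
  b <- generate_flow_movie(cfg)
  expect_identical(a$flow, b$flow)
  expect_identical(a$truth$events, b$truth$events)
  sa <- render_speckle(a$flow, cfg)
  sb <- render_speckle(b$flow, cfg)
  expect_identical(sa$frames, sb$frames)

  cfg2 <- small_cfg(8L)
  c2 <- generate_flow_movie(cfg2)
  expect_false(identical(render_speckle(c2$flow, cfg2)$frames, sa$frames))
  # same event ordering across seeds
  ord <- function(ev) order(c(ev$diameter_onset, ev$flow_onset,
                              ev$occlusion_onset, ev$occlusion_end))
  expect_identical(ord(a$truth$events), ord(c2$truth$events))
})

test_that("ground truth satisfies the structural invariants", {
  mv <- small_movie()
  ev <- mv$truth$events
  tr <- mv$truth$traces
  expect_lte(ev$diameter_onset, ev$flow_onset)
  expect_true(all(tr$d_um[tr$occluded] == 0))
  m <- mv$truth$region_masks
  expect_false(any(m$vessel & m$collateral))
  expect_false(any(m$cortex & m$vessel))
  expect_false(any(m$mca & m$aca))
  expect_true(all((m$mca | m$aca) == m$cortex))
  # collateral rises at the diameter-narrowing onset, before the flow drop
  expect_lt(abs(ev$collateral_onset - ev$diameter_onset), 15)
  expect_lt(ev$diameter_onset, ev$flow_onset)
})

test_that("rendered speckle rejects negative flow and stamps metadata", {
  cfg <- synth_config(seed = 1)
  expect_error(render_speckle(array(-1, dim = c(8, 8, 1)), cfg),
               "non-negative")
  st <- render_speckle(array(1, dim = c(16, 16, 3)), cfg,
                       timestamps = c(0, 0.1, 0.2))
  expect_s3_class(st, "speckle_stack")
  expect_equal(st$exposure_time_ms, 10)
  expect_equal(dim(st$frames), c(16L, 16L, 3L))
  expect_true(all(st$frames == round(st$frames)))
})

test_that("per-frame contrast of a static flow map is stationary", {
  st <- render_uniform_stack(25, frames = 100L, side = 48L, seed = 11)
  k_t <- apply(st$frames, 3, function(f) sd(f) / mean(f))
  fit <- stats::lm(k_t ~ seq_along(k_t))
  ci <- stats::confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("fixtures round-trip losslessly and refuse missing directories", {
  cfg <- synth_config(seed = 9, frame_size = c(32, 48), duration_s = 8,
                      baseline_duration_s = 2, rate_schedule = list(c(0, 5)),
                      light = list(mode = "off"))
  mv <- generate_flow_movie(cfg)
  st <- render_speckle(mv$flow, cfg)
  dir <- withr::local_tempdir()
  write_fixture(st, mv$truth, dir)
  back <- read_fixture(dir)
  expect_equal(back$stack$frames, st$frames, ignore_attr = TRUE)
  expect_lt(max(abs(back$stack$timestamps - st$timestamps)), 1e-9)
  expect_equal(back$truth$events$light_onset, 2)
  expect_equal(back$config$kinetics$k_on, cfg$kinetics$k_on)
  expect_equal(back$truth$region_masks$vessel,
               mv$truth$region_masks$vessel, ignore_attr = TRUE)
  expect_equal(back$truth$sd_rois[[2]], mv$truth$sd_rois[[2]],
               ignore_attr = TRUE)

  missing <- file.path(dir, "does-not-exist")
  expect_error(write_fixture(st, mv$truth, missing), "does not exist")
  expect_length(list.files(missing), 0L)
})
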