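test_that("a constructed crossing reproduces the occlusion metrics exactly", {
  tt <- seq(0, 600, 0.1)
  bf <- step_trace(tt, c(110, 120, 536.8), c(1, 0.15, 0.05, 0.5))
  d_tr <- step_trace(tt, c(110), c(1, 0.6))
  seg <- segment_phases(bf, d_tr, light_onset_s = 60)
  expect_identical(seg$status, "complete")
  expect_equal(seg$occlusion_onset, 120)
  expect_equal(seg$occlusion_end, 536.8)
  expect_equal(seg$occlusion_duration_d, 416.8)
  expect_equal(seg$time_to_occlusion_c, 60)
  expect_identical(seg$phases$phase,
                   c("baseline", "stenosis", "complete_occlusion",
                     "reperfusion"))
})

test_that("a flat trace yields a single baseline phase and no occlusion", {
  tt <- seq(0, 300, 0.5)
  flat <- data.frame(time_s = tt, value = rep(1, length(tt)))
  seg <- segment_phases(flat, light_onset_s = 30)
  expect_identical(seg$status, "no_occlusion")
  expect_identical(seg$phases$phase, "baseline")
  expect_true(is.na(seg$time_to_occlusion_c))
})

test_that("phase intervals partition the trace in order on random episodes", {
  set.seed(40)
  tt <- seq(0, 500, 0.5)
  for (i in 1:50) {
    on <- runif(1, 60, 120)
    off <- on + runif(1, 50, 300)
    depth <- runif(1, 0.0, 0.08)
    v <- ifelse(tt < on, 1, ifelse(tt < off, depth, runif(1, 0.3, 1)))
    v <- v + rnorm(length(tt), 0, 0.01)
    seg <- segment_phases(data.frame(time_s = tt, value = v),
                          light_onset_s = 30)
    ph <- seg$phases
    expect_equal(ph$start_s[1], tt[1])
    expect_equal(ph$end_s[nrow(ph)], tt[length(tt)])
    if (nrow(ph) > 1)
      expect_equal(ph$start_s[-1], ph$end_s[-nrow(ph)])
    allowed <- c("baseline", "stenosis", "complete_occlusion", "reperfusion")
    expect_true(all(diff(match(ph$phase, allowed)) > 0))
  }
})

test_that("onsets are located within a sample on constructed steps", {
  tt <- seq(0, 200, 0.1)
  d_tr <- step_trace(tt, 72.9, c(1, 0.8))
  ons <- onset_times(rel_d = d_tr, light_onset_s = 30)
  expect_lt(abs(ons$diameter_onset - 72.9), 0.11)

  coll <- step_trace(tt, 72.4, c(1, 1.3))
  bf <- step_trace(tt, 108.9, c(1, 0.7))
  ons2 <- onset_times(rel_d = NULL, rel_bf = bf, rel_collateral = coll,
                      light_onset_s = 30)
  expect_lt(ons2$collateral_onset, ons2$flow_onset)
  expect_lt(abs(ons2$collateral_onset - 72.4), 0.11)
  expect_lt(abs(ons2$flow_onset - 108.9), 0.11)
})

test_that("pure noise rarely produces a spurious onset", {
  set.seed(41)
  hits <- 0L
  tt <- seq(0, 120, 0.25)
  for (i in 1:100) {
    v <- 1 + rnorm(length(tt), 0, 0.015)
    ons <- onset_times(rel_d = data.frame(time_s = tt, value = v),
                       light_onset_s = 10)
    if (!is.na(ons$diameter_onset)) hits <- hits + 1L
  }
  expect_lt(hits / 100, 0.05)
})

test_that("occlusion metrics are stable under resampling to a lower rate", {
  run <- small_run()
  s <- run$trace$summary
  seg10 <- run$segmentation
  # resample the 4 Hz traces to 1 Hz
  keep <- seq(1, nrow(s), by = 4)
  seg1 <- segment_phases(data.frame(time_s = s$time_s[keep],
                                    value = s$rel_bf[keep]),
                         data.frame(time_s = s$time_s[keep],
                                    value = s$rel_d[keep]),
                         light_onset_s = 25)
  expect_lt(abs(seg1$occlusion_onset - seg10$occlusion_onset), 1.01)
  expect_lt(abs(seg1$occlusion_duration_d - seg10$occlusion_duration_d), 2.02)
})

test_that("episode comparison returns paired deltas and the stenosis flag", {
  tt <- seq(0, 600, 0.1)
  mk <- function(c_s, d_s, end_d) {
    bf <- step_trace(tt, c(30 + c_s, 30 + c_s + d_s), c(1, 0.05, 0.6))
    dd <- step_trace(tt, c(30 + c_s, 30 + c_s + d_s), c(1, 0, end_d))
    segment_phases(bf, dd, light_onset_s = 30)
  }
  seg1 <- mk(82.3, 400, 1.0)
  seg2 <- mk(41.5, 400, 0.7)
  cmp <- compare_episodes(seg1, seg2)
  expect_equal(cmp$delta_c, -40.8, tolerance = 0.02)
  expect_true(cmp$persistent_stenosis)

  same <- compare_episodes(seg1, seg1)
  expect_equal(same$delta_c, 0)
  expect_equal(same$delta_d, 0)
  expect_false(same$persistent_stenosis)

  flat <- segment_phases(data.frame(time_s = tt, value = rep(1, length(tt))),
                         light_onset_s = 30)
  expect_error(compare_episodes(seg1, flat), "occlusion")
})
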