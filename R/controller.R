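# Emulated real-time feedback loop: streaming single-frame contrast -> vessel
# blood flow at the light-spot ROI, debounced occlusion detection,
# illumination shutoff.

#' Initialize the feedback-controller state
#'
#' @param roi light-spot ROI (`list(line = ..., window = ...)`, 0-based).
#' @param um_per_pixel microns per pixel.
#' @param k consecutive sub-threshold frames required before stopping
#'   (debounce, default 5).
#' @param threshold relative blood-flow level defining complete occlusion
#'   (default 0.10).
#' @param max_duration_s illumination timeout from light onset (default 1800).
#' @param smooth_k causal trailing-median window on the relative BF stream
#'   (default 1 = none: the k-frame debounce is the noise rejection, and any
#'   smoothing adds detection lag).
#' @param hysteresis Schmitt-trigger band: starting the debounce counter
#'   requires `rel < threshold`, but once counting, samples up to
#'   `threshold + hysteresis` do not reset it (default 0.03). Measurement
#'   noise exactly at the threshold would otherwise restart the
#'   confirmation window and delay the stop.
#' @param contrast_w spatial contrast window for the real-time path
#'   (default 7; temporal depth is 1 frame for causality).
#' @return object of class `controller_state`.
#' @export
controller_init <- function(roi, um_per_pixel, k = 5L, threshold = 0.10,
                            max_duration_s = 1800, smooth_k = 1L,
                            contrast_w = 7L, hysteresis = 0.03) {
  structure(list(roi = roi, um_per_pixel = um_per_pixel, k = as.integer(k),
                 threshold = threshold, hysteresis = hysteresis,
                 max_duration_s = max_duration_s,
                 smooth_k = as.integer(smooth_k), contrast_w = contrast_w,
                 baseline_bf = NA_real_, light_onset_s = NA_real_,
                 consecutive_below = 0L, illumination_on = FALSE,
                 stop_time = NA_real_, stopped = FALSE, timeout = FALSE,
                 buffer = numeric(0), hist_t = numeric(0),
                 hist_rel = numeric(0), hist_rel_smooth = numeric(0)),
            class = "controller_state")
}

controller_measure_bf <- function(state, frame) {
  # restrict the contrast computation to the ROI window plus the contrast
  # radius: the controller never looks outside its light-spot region
  rr <- (state$contrast_w - 1L) %/% 2L
  w <- state$roi$window
  r0 <- max(1L, w$y0 + 1L - rr); r1 <- min(nrow(frame), w$y1 + 1L + rr)
  c0 <- max(1L, w$x0 + 1L - rr); c1 <- min(ncol(frame), w$x1 + 1L + rr)
  sub <- frame[r0:r1, c0:c1, drop = FALSE]
  k_map <- spatial_contrast(sub, state$contrast_w)
  bfi <- contrast_to_bfi(k_map)
  roi_loc <- list(window = list(x0 = w$x0 - (c0 - 1L), x1 = w$x1 - (c0 - 1L),
                                y0 = w$y0 - (r0 - 1L), y1 = w$y1 - (r0 - 1L)))
  m <- measure_roi_box(bfi, roi_loc, state$um_per_pixel)
  blood_flow(m$diameter_um, m$bfi)
}

#' Establish the controller's baseline blood flow from pre-light frames
#'
#' @param state a `controller_state`.
#' @param frames list of raw speckle frames acquired before light onset.
#' @return updated state with `baseline_bf` set.
#' @export
controller_baseline <- function(state, frames) {
  stopifnot(inherits(state, "controller_state"))
  if (!length(frames)) stop("need at least one baseline frame")
  bfs <- vapply(frames, function(f) controller_measure_bf(state, f),
                numeric(1))
  state$baseline_bf <- mean(bfs)
  if (!is.finite(state$baseline_bf) || state$baseline_bf <= 0)
    stop("failed to establish a positive baseline blood flow")
  state
}

#' Advance the controller by one incoming frame
#'
#' Computes the ROI blood flow from single-frame spatial contrast, updates
#' the debounce counter while the relative BF is below the occlusion
#' threshold, and issues `stop` after `k` consecutive sub-threshold frames
#' or on timeout. Illumination is never re-enabled after a stop.
#'
#' @param state a `controller_state` with an established baseline.
#' @param frame raw speckle frame (matrix).
#' @param timestamp frame time, seconds.
#' @return list with `state` (updated) and `command` (`"keep_on"` or
#'   `"stop"`).
#' @export
controller_step <- function(state, frame, timestamp) {
  stopifnot(inherits(state, "controller_state"))
  if (!is.finite(state$baseline_bf))
    stop("baseline not established: feed pre-light frames first")
  if (is.na(state$light_onset_s)) state$light_onset_s <- timestamp
  if (state$stopped)
    return(list(state = state, command = "stop"))

  bf <- controller_measure_bf(state, frame)
  rel <- bf / state$baseline_bf
  state$buffer <- c(utils::tail(state$buffer, state$smooth_k - 1L), rel)
  rel_s <- stats::median(state$buffer)
  lim <- state$threshold +
    if (state$consecutive_below > 0L) state$hysteresis else 0
  state$consecutive_below <-
    if (rel_s < lim) state$consecutive_below + 1L else 0L
  state$hist_t <- c(state$hist_t, timestamp)
  state$hist_rel <- c(state$hist_rel, rel)
  state$hist_rel_smooth <- c(state$hist_rel_smooth, rel_s)
  command <- "keep_on"
  if (state$consecutive_below >= state$k) {
    command <- "stop"
    state$stopped <- TRUE
    state$stop_time <- timestamp
  } else if (timestamp - state$light_onset_s >= state$max_duration_s) {
    command <- "stop"
    state$stopped <- TRUE
    state$timeout <- TRUE
    state$stop_time <- timestamp
  }
  state$illumination_on <- !state$stopped
  list(state = state, command = command)
}

#' Run the closed loop: simulator driven frame-by-frame by the controller
#'
#' The thrombosis kinetics are integrated between frames with the
#' illumination gated by the controller's commands; each frame is rendered
#' from the current occupancy and fed back to the controller. After the stop
#' (or timeout) the recording continues so spontaneous recanalization is
#' observed. Ground-truth events are extracted from the noise-free rendered
#' traces exactly as in [generate_flow_movie()].
#'
#' @param cfg a [synth_config()]; its `light$mode` is ignored (the controller
#'   owns the light).
#' @param controller_params list overriding `k`, `threshold`,
#'   `max_duration_s`, `smooth_k`.
#' @param keep_stack keep the rendered frames in the result (default FALSE).
#' @return list with `report` (stop time, ground-truth occlusion onset/end,
#'   realized c and d, detection latency, timeout flag), `state`, `truth`
#'   (per-frame noise-free traces and events), optionally `stack`.
#' @export
run_closed_loop <- function(cfg, controller_params = list(),
                            keep_stack = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  rates <- jitter_rates(cfg)
  geo <- synth_geometry(cfg)
  ts <- schedule_timestamps(cfg$rate_schedule, cfg$duration_s)
  nT <- length(ts)
  cp <- utils::modifyList(list(k = 5L, threshold = 0.10,
                               max_duration_s = cfg$light$max_duration_s,
                               smooth_k = 1L, hysteresis = 0.03),
                          controller_params)
  roi <- geo$light_spot_roi  # monitoring window spans the light spot
  ctrl <- controller_init(roi, cfg$um_per_pixel, k = cp$k,
                          threshold = cp$threshold,
                          max_duration_s = cp$max_duration_s,
                          smooth_k = cp$smooth_k, hysteresis = cp$hysteresis)

  light_onset <- cfg$baseline_duration_s
  kin <- kinetics_init(cfg, rates)
  v <- cfg$vessel
  sp <- cfg$speckle; nz <- cfg$noise
  cap <- 2^sp$bit_depth - 1

  theta_t <- numeric(nT); w_px_t <- integer(nT)
  flux_t <- numeric(nT); vel_t <- numeric(nT); bf_rend_t <- numeric(nT)
  flow_arr <- array(0, dim = c(geo$nr, geo$nc, nT))
  frames <- if (keep_stack) array(0, dim = c(geo$nr, geo$nc, nT)) else NULL
  base_frame <- matrix(1, geo$nr, geo$nc)
  par_mask <- !(geo$masks$vessel | geo$masks$collateral)
  sev <- geo$severity
  illum <- TRUE  # command state: light allowed (gated by onset time too)

  render_frame <- function(i) {
    th <- theta_t[i]
    d_px <- (1 - th) * geo$d0_px
    w_px_t[i] <<- length(geo$footprint_cols(d_px))
    flux_t[i] <<- vessel_flux(th, v)
    h <- if (is.na(kin$t_detach)) 1 else
      hyperemia_env(ts[i] - kin$t_detach, cfg$hyperemia)
    bf_eff <- min(flux_t[i] * h, 2)
    w_rel <- w_px_t[i] / geo$w0
    vel_t[i] <<- min(vessel_velocity(w_rel, v) * h, v$velocity_cap)
    bf_rend_t[i] <<- w_rel^2 * vel_t[i]
    drive <- min(max(bf_eff, 0), 1.25)
    fr <- base_frame
    fr[par_mask] <- 1 - sev[par_mask] * (1 - drive)
    fr[geo$masks$collateral] <- cfg$collateral$flow_gain *
      (1 + cfg$collateral$gain * th)
    fr[, geo$base_cols] <- 1 - cfg$cortex$window_severity * (1 - drive)
    lum <- geo$footprint_cols(d_px)
    if (length(lum)) fr[, lum] <- v$flow_gain * vel_t[i]
    flow_arr[, , i] <<- fr
    # render speckle for this frame
    n_avg <- round(1 + sp$g * fr)
    intensity <- stats::rgamma(length(n_avg), shape = n_avg, rate = n_avg)
    counts <- sp$mean_counts * intensity
    if (nz$shot_scale > 0)
      counts <- counts + stats::rnorm(length(counts), 0,
                                      nz$shot_scale * sqrt(pmax(counts, 1)))
    counts <- counts + nz$dark_offset
    matrix(pmin(pmax(round(counts), 0), cap), geo$nr, geo$nc)
  }

  baseline_frames <- list()
  for (i in seq_len(nT)) {
    light_cmd <- function(t, theta) {
      t >= light_onset && illum
    }
    kin <- kinetics_advance(kin, ts[i], light_cmd, cfg)
    theta_t[i] <- kin$theta
    raw <- render_frame(i)
    if (keep_stack) frames[, , i] <- raw
    if (ts[i] < light_onset) {
      baseline_frames[[length(baseline_frames) + 1L]] <- raw
      next
    }
    if (!is.finite(ctrl$baseline_bf)) {
      if (!length(baseline_frames)) stop("no baseline frames before light")
      ctrl <- controller_baseline(ctrl, baseline_frames)
      ctrl$light_onset_s <- light_onset
    }
    if (illum || !ctrl$stopped) {
      res <- controller_step(ctrl, raw, ts[i])
      ctrl <- res$state
      if (res$command == "stop") illum <- FALSE
    }
  }

  mt <- measurement_truth(flow_arr, ts, cfg, geo, light_onset)
  occl_on <- mt$segmentation$occlusion_onset
  occl_end <- mt$segmentation$occlusion_end

  # causal ground truth: what a noise-free real-time monitor (single-frame
  # spatial contrast, same ROI estimator) would measure; the offline truth's
  # centred temporal window sees lumen transitions ~2 frames early, which no
  # causal detector can match
  exp_rt <- expected_bfi_series(flow_arr, cfg, ts, window = c(7L, 7L, 1L))
  # evaluate the causal measurement only where it is needed: the baseline
  # (for normalization) and a window around the offline occlusion onset
  eval_idx <- which(exp_rt$frame_times < light_onset |
                      (!is.na(occl_on) &
                         exp_rt$frame_times >= occl_on - 30 &
                         exp_rt$frame_times <= occl_on + 15))
  if (is.na(occl_on)) eval_idx <- seq_along(exp_rt$frame_times)
  bf_rt <- rep(NA_real_, length(exp_rt$frame_times))
  for (i in eval_idx) {
    m <- measure_roi_box(exp_rt$bfi[, , i], roi, cfg$um_per_pixel)
    bf_rt[i] <- blood_flow(m$diameter_um, m$bfi)
  }
  base_rt <- mean(bf_rt[exp_rt$frame_times < light_onset])
  rel_rt <- bf_rt / base_rt
  occl_on_rt <- sustained_onset(exp_rt$frame_times,
                                exp_rt$frame_times >= light_onset &
                                  !is.na(rel_rt) & rel_rt < cp$threshold, 2)
  frame_dt <- stats::median(diff(ts))
  report <- list(
    stop_time = ctrl$stop_time,
    timeout = ctrl$timeout,
    light_onset = light_onset,
    occlusion_onset = occl_on,
    occlusion_end = occl_end,
    occlusion_onset_rt = occl_on_rt,
    c_s = if (is.na(occl_on)) NA_real_ else occl_on - light_onset,
    d_s = if (is.na(occl_on) || is.na(occl_end)) NA_real_ else
      occl_end - occl_on,
    latency_s = if (is.na(occl_on_rt) || is.na(ctrl$stop_time)) NA_real_ else
      ctrl$stop_time - occl_on_rt,
    latency_offline_s = if (is.na(occl_on) || is.na(ctrl$stop_time))
      NA_real_ else ctrl$stop_time - occl_on,
    median_frame_dt = frame_dt)
  truth <- list(time_s = ts,
                traces = data.frame(time_s = ts, theta = theta_t,
                                    w_px = w_px_t, flux = flux_t,
                                    bf_rel = bf_rend_t,
                                    velocity_rel = vel_t),
                measured = mt$measured,
                events = list(light_onset = light_onset,
                              light_off = kin$t_off, detach = kin$t_detach,
                              occlusion_onset = occl_on,
                              occlusion_end = occl_end))
  out <- list(report = report, state = ctrl, truth = truth)
  if (keep_stack)
    out$stack <- speckle_stack(frames, ts, cfg$exposure_time_ms,
                               cfg$um_per_pixel, sp$bit_depth)
  out
}
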