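# TIA phase segmentation, onset times and two-episode comparison.
#
# Phases (on the relative vessel blood flow, with the relative diameter as a
# co-trigger for the end of baseline):
#   baseline          flow ~ 1 before and shortly after light onset
#   stenosis          from the first sustained decrease of flow or diameter
#   complete occlusion relative BF < 10% of baseline, sustained
#   reperfusion       from the first sustained recovery above 10%
# c = occlusion start - light onset; d = occlusion duration.

default_onset_params <- function() {
  list(onset_eps = 0.05, sustain_s = 2, smooth_k = 5,
       occlusion_threshold = 0.10)
}

# First sustained deviation of a relative trace after `after`.
detect_onset <- function(time_s, x, direction = c("down", "up"),
                         eps = 0.05, sustain_s = 2, smooth_k = 5,
                         after = -Inf) {
  direction <- match.arg(direction)
  xs <- moving_median(x, smooth_k)
  flag <- if (direction == "down") xs < 1 - eps else xs > 1 + eps
  flag[time_s < after] <- FALSE
  sustained_onset(time_s, flag, sustain_window(time_s, sustain_s, smooth_k))
}

# sustained windows span a duration, but never less than twice the
# smoothing correlation length: after a k-sample moving median, adjacent
# samples share k-1 inputs, so a single noise excursion already persists
# ~k samples and a shorter window would accept it
sustain_window <- function(time_s, sustain_s, smooth_k = 5L) {
  max(sustain_s, 2 * smooth_k * stats::median(diff(time_s)))
}

#' Onset times of diameter narrowing, flow reduction and collateral rise
#'
#' Each onset is the first time after light onset at which the smoothed
#' relative trace deviates beyond `onset_eps` from 1 (below for decreases,
#' above for the collateral increase) and the deviation is sustained for at
#' least `sustain_s` seconds. Missing deviations are reported as `NA`.
#'
#' @param rel_d relative vessel diameter data.frame (`time_s`, `value`), or
#'   `NULL`.
#' @param rel_bf relative vessel blood flow, same layout, or `NULL`.
#' @param rel_collateral relative collateral BFI, same layout, or `NULL`.
#' @param light_onset_s illumination start, seconds.
#' @param params list overriding [default_onset_params()].
#' @return list with `diameter_onset`, `flow_onset`, `collateral_onset`
#'   (seconds, `NA` when absent).
#' @export
onset_times <- function(rel_d = NULL, rel_bf = NULL, rel_collateral = NULL,
                        light_onset_s = 0, params = list()) {
  p <- utils::modifyList(default_onset_params(), params)
  pick <- function(df, dir) {
    if (is.null(df)) return(NA_real_)
    detect_onset(df$time_s, df$value, dir, p$onset_eps, p$sustain_s,
                 p$smooth_k, after = light_onset_s)
  }
  list(diameter_onset = pick(rel_d, "down"),
       flow_onset = pick(rel_bf, "down"),
       collateral_onset = pick(rel_collateral, "up"))
}

#' Segment a TIA time course into phases
#'
#' @param rel_bf data.frame (`time_s`, `value`): relative vessel blood flow.
#' @param rel_d optional relative diameter trace (same timestamps).
#' @param light_onset_s illumination start, seconds.
#' @param params list overriding [default_onset_params()].
#' @return object of class `phase_segmentation`: `phases` data.frame
#'   (`phase`, `start_s`, `end_s`), onset times, `time_to_occlusion_c`,
#'   `occlusion_duration_d`, `status` (`"complete"`, `"no_occlusion"`, or
#'   `"unresolved"` when the trace ends occluded), `end_rel_d`.
#' @export
segment_phases <- function(rel_bf, rel_d = NULL, light_onset_s = 0,
                           params = list()) {
  p <- utils::modifyList(default_onset_params(), params)
  tt <- rel_bf$time_s
  if (!is.null(rel_d) &&
      (nrow(rel_d) != nrow(rel_bf) ||
       max(abs(rel_d$time_s - tt)) > 1e-6))
    stop("traces must share timestamps")
  if (light_onset_s <= tt[1L])
    stop("baseline window must precede light onset")

  flow_onset <- detect_onset(tt, rel_bf$value, "down", p$onset_eps,
                             p$sustain_s, p$smooth_k, after = light_onset_s)
  diameter_onset <- if (is.null(rel_d)) NA_real_ else
    detect_onset(tt, rel_d$value, "down", p$onset_eps, p$sustain_s,
                 p$smooth_k, after = light_onset_s)
  baseline_end <- suppressWarnings(min(flow_onset, diameter_onset,
                                       na.rm = TRUE))
  if (!is.finite(baseline_end)) baseline_end <- NA_real_

  bf_s <- moving_median(rel_bf$value, p$smooth_k)
  sus <- sustain_window(tt, p$sustain_s, p$smooth_k)
  occ_on <- sustained_onset(tt, bf_s < p$occlusion_threshold &
                              tt >= light_onset_s, sus)
  occ_end <- NA_real_
  status <- "no_occlusion"
  if (!is.na(occ_on)) {
    occ_end <- sustained_onset(tt, bf_s >= p$occlusion_threshold &
                                 tt > occ_on, sus)
    status <- if (is.na(occ_end)) "unresolved" else "complete"
  }

  t_end <- tt[length(tt)]
  phases <- data.frame(phase = character(0), start_s = numeric(0),
                       end_s = numeric(0))
  add <- function(ph, a, b) {
    if (!is.na(a) && !is.na(b) && b > a)
      rbind(phases, data.frame(phase = ph, start_s = a, end_s = b))
    else phases
  }
  if (is.na(baseline_end)) {
    phases <- add("baseline", tt[1L], t_end)
  } else {
    phases <- add("baseline", tt[1L], baseline_end)
    phases <- add("stenosis", baseline_end,
                  if (is.na(occ_on)) t_end else occ_on)
    if (!is.na(occ_on)) {
      phases <- add("complete_occlusion", occ_on,
                    if (is.na(occ_end)) t_end else occ_end)
      if (!is.na(occ_end)) phases <- add("reperfusion", occ_end, t_end)
    }
  }

  end_rel_d <- if (is.null(rel_d)) NA_real_ else
    stats::median(utils::tail(rel_d$value, max(3L, p$smooth_k)))

  structure(list(
    phases = phases,
    light_onset_s = light_onset_s,
    diameter_onset = diameter_onset,
    flow_onset = flow_onset,
    occlusion_onset = occ_on,
    occlusion_end = occ_end,
    time_to_occlusion_c = if (is.na(occ_on)) NA_real_ else
      occ_on - light_onset_s,
    occlusion_duration_d = if (is.na(occ_on)) NA_real_ else
      (if (is.na(occ_end)) t_end else occ_end) - occ_on,
    status = status,
    end_rel_d = end_rel_d), class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation>", x$status, "\n")
  print(x$phases, row.names = FALSE)
  if (!is.na(x$occlusion_onset))
    cat(sprintf("  c = %.1f s, d = %.1f s\n", x$time_to_occlusion_c,
                x$occlusion_duration_d))
  invisible(x)
}

#' Compare two ischemic episodes at the same site
#'
#' Paired differences of time-to-occlusion and occlusion duration between a
#' first and a second episode, plus a persistent-stenosis flag on the second
#' episode's end-of-trace relative diameter.
#'
#' @param seg1,seg2 `phase_segmentation` objects with complete occlusions.
#' @param stenosis_eps relative-diameter deficit defining persistent
#'   stenosis at the end of the recording (default 0.1).
#' @return list with `delta_c`, `delta_d`, `persistent_stenosis`.
#' @export
compare_episodes <- function(seg1, seg2, stenosis_eps = 0.1) {
  for (s in list(seg1, seg2))
    if (is.na(s$occlusion_onset) || s$status == "no_occlusion")
      stop("both segmentations must contain a complete occlusion")
  list(delta_c = seg2$time_to_occlusion_c - seg1$time_to_occlusion_c,
       delta_d = seg2$occlusion_duration_d - seg1$occlusion_duration_d,
       persistent_stenosis = isTRUE(seg2$end_rel_d < 1 - stenosis_eps))
}
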