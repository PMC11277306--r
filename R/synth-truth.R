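# Noise-free measurement-equivalent truth.
#
# The speckle encoding fixes the expected contrast of every pixel:
# K^2 = 1/N with N = round(1 + g * flow). A (7,7,5) contrast cube mixes
# per-pixel variances linearly (all pixels share the same mean), so the
# expected windowed contrast is K^2 = boxmean(1/N) and the expected BFI map
# is its reciprocal. Running the actual measurement chain (vessel_trace,
# segment_phases, onset_times) on these deterministic maps gives the events
# a noiseless acquisition would record; recovery tests then quantify pure
# estimation error from speckle noise and sampling.

#' Expected (noise-free) BFI series implied by a flow movie
#'
#' @param flow H x W x T relative-flow array.
#' @param cfg a [synth_config()] (supplies the flow-to-N gain).
#' @param timestamps per-frame times.
#' @param window contrast window, default `c(7, 7, 5)`.
#' @return a `bfi_series` of expected BFI maps (temporally valid frames).
#' @export
expected_bfi_series <- function(flow, cfg, timestamps,
                                window = c(7L, 7L, 5L)) {
  d <- dim(flow)
  inv_n <- 1 / round(1 + cfg$speckle$g * flow)
  rt <- (window[3L] - 1L) %/% 2L
  rr <- (window[1L] - 1L) %/% 2L
  n_out <- d[3L] - window[3L] + 1L
  n_cube <- prod(window)
  bfi <- array(0, dim = c(d[1L], d[2L], n_out))
  s1 <- matrix(0, d[1L], d[2L])
  for (j in seq_len(window[3L])) s1 <- s1 + inv_n[, , j]
  for (i in seq_len(n_out)) {
    k2 <- box_sum(s1, rr) / n_cube
    bfi[, , i] <- pmin(1 / k2, 1e4)
    if (i < n_out) s1 <- s1 + inv_n[, , i + window[3L]] - inv_n[, , i]
  }
  structure(list(bfi = bfi,
                 frame_times = timestamps[(rt + 1L):(rt + n_out)],
                 mapping = "inv_k2"),
            class = "bfi_series")
}

# Measurement-equivalent truth: run the analysis chain on the expected BFI.
measurement_truth <- function(flow, ts, cfg, geo, light_onset) {
  exp_bfi <- expected_bfi_series(flow, cfg, ts)
  base_win <- c(exp_bfi$frame_times[1L], light_onset - 1)
  tr0 <- vessel_trace(exp_bfi, geo$rois, base_win, cfg$um_per_pixel)
  rel_bf0 <- data.frame(time_s = tr0$summary$time_s,
                        value = tr0$summary$rel_bf)
  rel_d0 <- data.frame(time_s = tr0$summary$time_s,
                       value = tr0$summary$rel_d)
  rel_coll0 <- relative_series(exp_bfi, base_win, geo$collateral_roi)
  seg0 <- segment_phases(rel_bf0, rel_d0, light_onset_s = light_onset)
  ons0 <- onset_times(rel_d0, rel_bf0, rel_coll0,
                      light_onset_s = light_onset)
  list(segmentation = seg0, onsets = ons0,
       measured = data.frame(time_s = tr0$summary$time_s,
                             rel_d = tr0$summary$rel_d,
                             rel_bf = tr0$summary$rel_bf,
                             rel_coll = rel_coll0$value),
       baseline_window = base_win)
}
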