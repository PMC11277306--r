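# Spatiotemporal speckle contrast -> blood flow index (BFI).

#' Spatiotemporal speckle contrast of a stack
#'
#' For every voxel, the contrast is `K = sigma / mu` computed over a
#' `window[1] x window[2] x window[3]` (rows x cols x frames) cube of raw
#' intensities, with population (divide-by-n) standard deviation. Spatial
#' borders are handled by edge replication; the temporal window is centred
#' and only valid positions are emitted, so the output has
#' `T - window[3] + 1` frames. Cubes with non-positive mean get `K = 0` and a
#' warning (dark pixels).
#'
#' Values are internally centred on the stack mean before the sums are
#' accumulated, which keeps the summed-area-table evaluation accurate to
#' near machine precision.
#'
#' @param stack a `speckle_stack` (or plain H x W x T array with attribute-free
#'   frames; then `timestamps` must be supplied).
#' @param window odd integers `c(rows, cols, frames)`; default `c(7, 7, 5)`.
#' @param timestamps optional, when `stack` is a bare array.
#' @return object of class `contrast_series`: list with `k` (H x W x T'
#'   array), `frame_times`, `window`.
#' @export
compute_contrast <- function(stack, window = c(7L, 7L, 5L),
                             timestamps = NULL) {
  if (inherits(stack, "speckle_stack")) {
    frames <- stack$frames; ts <- stack$timestamps
  } else {
    frames <- stack; ts <- timestamps
  }
  d <- dim(frames)
  if (is.null(d) || length(d) != 3L) stop("stack must be H x W x T")
  window <- as.integer(window)
  if (any(window < 1L) || any(window[1:2] %% 2L == 0L) ||
      window[3L] %% 2L == 0L)
    stop("window sizes must be odd positive integers")
  if (d[3L] < window[3L]) stop("need at least ", window[3L], " frames")
  if (d[1L] < window[1L] || d[2L] < window[2L])
    stop("frame smaller than the spatial window")
  if (is.null(ts)) ts <- seq_len(d[3L]) - 1
  rr <- (window[1L] - 1L) %/% 2L
  rt <- (window[3L] - 1L) %/% 2L
  n_out <- d[3L] - window[3L] + 1L
  n_cube <- window[1L] * window[2L] * window[3L]

  centre <- mean(frames)
  fx <- frames - centre

  # running temporal slab sums, then 7x7 spatial box sums via SAT
  k_out <- array(0, dim = c(d[1L], d[2L], n_out))
  s1 <- matrix(0, d[1L], d[2L]); s2 <- matrix(0, d[1L], d[2L])
  for (j in seq_len(window[3L])) {
    s1 <- s1 + fx[, , j]
    s2 <- s2 + fx[, , j]^2
  }
  n_dark <- 0L
  for (i in seq_len(n_out)) {
    b1 <- box_sum(s1, rr)
    b2 <- box_sum(s2, rr)
    mu <- b1 / n_cube + centre
    varr <- pmax(b2 / n_cube - (b1 / n_cube)^2, 0)
    k <- sqrt(varr) / mu
    bad <- mu <= 0
    if (any(bad)) { n_dark <- n_dark + sum(bad); k[bad] <- 0 }
    k_out[, , i] <- k
    if (i < n_out) {
      s1 <- s1 + fx[, , i + window[3L]] - fx[, , i]
      s2 <- s2 + fx[, , i + window[3L]]^2 - fx[, , i]^2
    }
  }
  if (n_dark > 0L)
    warning(sprintf("%d cubes had non-positive mean; contrast set to 0",
                    n_dark))
  structure(list(k = k_out, frame_times = ts[(rt + 1L):(rt + n_out)],
                 window = window),
            class = "contrast_series")
}

#' Single-frame spatial speckle contrast
#'
#' Causal variant used by the real-time controller: `K = sigma / mu` over a
#' `w x w` spatial window of one frame (temporal depth 1), edge-replicated.
#'
#' @param frame numeric matrix of raw intensities.
#' @param w odd spatial window size, default 7.
#' @return matrix of contrast values.
#' @export
spatial_contrast <- function(frame, w = 7L) {
  r <- (as.integer(w) - 1L) %/% 2L
  n <- w * w
  centre <- mean(frame)
  fx <- frame - centre
  mu <- box_sum(fx, r) / n + centre
  varr <- pmax(box_sum(fx^2, r) / n - (mu - centre)^2, 0)
  k <- sqrt(varr) / mu
  k[mu <= 0] <- 0
  k
}

#' Map speckle contrast to a blood flow index
#'
#' Default mapping is the standard LSCI estimator `BFI = 1 / K^2`; `1 / K`
#' is available as an alternative. Contrast below `k_floor` is capped to
#' `bfi_cap` so the output stays finite.
#'
#' @param contrast a `contrast_series` or bare contrast array/matrix.
#' @param mapping `"inv_k2"` (default) or `"inv_k"`.
#' @param k_floor contrast floor below which the cap applies.
#' @param bfi_cap value assigned where `K < k_floor`.
#' @return object of class `bfi_series` (list with `bfi`, `frame_times`) when
#'   the input is a `contrast_series`, otherwise an array like the input.
#' @export
contrast_to_bfi <- function(contrast, mapping = c("inv_k2", "inv_k"),
                            k_floor = 1e-3, bfi_cap = 1e4) {
  mapping <- match.arg(mapping)
  k <- if (inherits(contrast, "contrast_series")) contrast$k else contrast
  if (any(k < 0)) stop("contrast must be non-negative")
  bfi <- switch(mapping, inv_k2 = 1 / k^2, inv_k = 1 / k)
  bfi[k < k_floor] <- bfi_cap
  bfi <- pmin(bfi, bfi_cap)
  if (inherits(contrast, "contrast_series"))
    structure(list(bfi = bfi, frame_times = contrast$frame_times,
                   mapping = mapping),
              class = "bfi_series")
  else bfi
}

#' Baseline-normalized ROI trace from a BFI series
#'
#' Per-frame mean BFI over an ROI, divided by its mean over the baseline
#' window, giving a relative trace that is ~1 before intervention.
#'
#' @param bfi_series a `bfi_series`.
#' @param baseline_window `c(t0, t1)` in seconds.
#' @param roi logical mask (H x W) or 2-column index matrix.
#' @return data.frame with `time_s`, `value`.
#' @export
relative_series <- function(bfi_series, baseline_window, roi) {
  stopifnot(inherits(bfi_series, "bfi_series"))
  d <- dim(bfi_series$bfi)
  idx <- roi_indices(roi, d[1:2])
  if (!nrow(idx)) stop("roi is empty")
  flat <- matrix(bfi_series$bfi, d[1L] * d[2L], d[3L])
  lin <- (idx[, 2L] - 1L) * d[1L] + idx[, 1L]
  trace <- colMeans(flat[lin, , drop = FALSE])
  tt <- bfi_series$frame_times
  in_base <- tt >= baseline_window[1L] & tt <= baseline_window[2L]
  if (!any(in_base)) stop("baseline window contains no frames")
  base <- mean(trace[in_base])
  if (!is.finite(base) || base == 0) stop("baseline mean is zero")
  data.frame(time_s = tt, value = trace / base)
}

roi_indices <- function(roi, dim2) {
  if (is.logical(roi)) {
    if (!all(dim(roi) == dim2)) stop("roi mask dimensions mismatch")
    which(roi, arr.ind = TRUE)
  } else if (is.matrix(roi) && ncol(roi) == 2L) {
    roi
  } else stop("roi must be a logical mask or a 2-column index matrix")
}

#' Pixelwise relative-BFI series against a baseline map
#'
#' Divides every frame of a BFI series by the per-pixel mean over the
#' baseline window, the input expected by [classify_ischemia()] and
#' [correlation_map()].
#'
#' @param bfi_series a `bfi_series`.
#' @param baseline_window `c(t0, t1)` seconds.
#' @return a `bfi_series` whose values are relative to baseline.
#' @export
relative_bfi_series <- function(bfi_series, baseline_window) {
  stopifnot(inherits(bfi_series, "bfi_series"))
  tt <- bfi_series$frame_times
  in_base <- tt >= baseline_window[1L] & tt <= baseline_window[2L]
  if (!any(in_base)) stop("baseline window contains no frames")
  d <- dim(bfi_series$bfi)
  base <- apply(bfi_series$bfi[, , in_base, drop = FALSE], c(1L, 2L), mean)
  if (any(base <= 0)) stop("baseline map has non-positive pixels")
  rel <- bfi_series$bfi / array(base, dim = d)
  structure(list(bfi = rel, frame_times = tt, mapping = bfi_series$mapping,
                 baseline_map = base),
            class = "bfi_series")
}
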