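# Vessel segmentation, diameter and blood flow (BF = pi D^2 / 4 * BFI).

#' Otsu threshold of an image
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' min-max scaled values; ties are broken by the lowest maximizing bin. The
#' returned threshold is the upper edge of that bin on the original scale,
#' so the foreground is `x > threshold`.
#'
#' @param x numeric matrix or vector with at least two distinct values.
#' @param n_bins histogram bins, default 256.
#' @return threshold value (original scale).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("no bimodality: image is constant")
  u <- (x - lo) / (hi - lo)
  bin <- pmin(pmax(floor(u * n_bins) + 1L, 1L), n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  # exact per-bin value sums: class means are those of the actual pixels, so
  # the maximized objective equals a pixel-level exhaustive search over the
  # same candidate bin edges
  vsum <- numeric(n_bins)
  rs <- rowsum(u, bin)
  vsum[as.integer(rownames(rs))] <- rs[, 1L]
  p <- cnt / length(x)
  w0 <- cumsum(p)
  mu_c <- cumsum(vsum) / length(x)
  mu_t <- mu_c[n_bins]
  t_idx <- seq_len(n_bins - 1L)
  w0t <- w0[t_idx]; w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  sb <- rep(-Inf, n_bins - 1L)
  sb[valid] <- (mu_t * w0t[valid] - mu_c[t_idx][valid])^2 /
    (w0t[valid] * w1t[valid])
  best <- which.max(sb)           # which.max returns the first (lowest) max
  lo + (best / n_bins) * (hi - lo)
}

#' Vessel diameter along a section line
#'
#' Length of the longest contiguous foreground run along the rasterized
#' section line, in microns; 0 when the line carries no foreground
#' (complete occlusion).
#'
#' @param mask logical matrix (TRUE = vessel).
#' @param line list with `x0, y0, x1, y1` (0-based pixel coordinates).
#' @param um_per_pixel microns per pixel (> 0).
#' @return diameter in microns.
#' @export
measure_diameter <- function(mask, line, um_per_pixel) {
  if (um_per_pixel <= 0) stop("um_per_pixel must be positive")
  px <- raster_line(line, dim(mask))
  vals <- mask[cbind(px[, "row"], px[, "col"])]
  longest_run(vals) * um_per_pixel
}

#' Vessel blood flow from diameter and BFI
#'
#' `BF = pi * D^2 / 4 * BFI`: the blood flow index scaled by the vessel's
#' cross-sectional area.
#'
#' @param diameter_um vessel diameter in microns (>= 0, vectorized).
#' @param bfi blood flow index (>= 0, vectorized).
#' @return blood flow in a.u. * um^2.
#' @export
blood_flow <- function(diameter_um, bfi) {
  if (any(diameter_um < 0) || any(bfi < 0))
    stop("diameter and BFI must be non-negative")
  pi * diameter_um^2 / 4 * bfi
}

crop_rect <- function(m, win) {
  rows <- (win$y0 + 1L):(win$y1 + 1L)
  cols <- (win$x0 + 1L):(win$x1 + 1L)
  if (min(rows) < 1L || max(rows) > nrow(m) ||
      min(cols) < 1L || max(cols) > ncol(m))
    stop("ROI window outside image")
  list(vals = m[rows, cols, drop = FALSE], rows = rows, cols = cols)
}

# Diameter + line-mean BFI of one ROI on one BFI frame. Per-frame Otsu on the
# window crop, applied in the K^2 = 1/BFI domain: windowed contrast mixes
# vessel and parenchyma variances linearly in the vessel fill fraction, so
# the between-class threshold falls at ~50% fill and the binarized width
# matches the rendered lumen. The vessel class is the binary class holding
# the majority of the three central line pixels, which stays correct if an
# occluded vessel turns darker than the surrounding ischemic parenchyma.
measure_roi_frame <- function(bfi_map, roi, um_per_pixel,
                              min_contrast = 2.2, dom = NULL) {
  if (is.null(dom)) dom <- 1 / pmax(bfi_map, .Machine$double.eps)
  cr <- crop_rect(dom, roi$window)
  thr <- tryCatch(otsu_threshold(cr$vals), error = function(e) NA_real_)
  if (is.na(thr))
    return(list(diameter_um = 0, bfi = mean(crop_rect(bfi_map, roi$window)$vals)))
  px <- raster_line(roi$line, dim(bfi_map))
  fg <- dom > thr
  vals_line <- fg[cbind(px[, "row"], px[, "col"])]
  mid <- nrow(px) %/% 2L + 1L
  sel <- unique(pmin(pmax(c(mid - 1L, mid, mid + 1L), 1L), nrow(px)))
  vessel_is_fg <- mean(vals_line[sel]) >= 0.5
  on_vessel <- if (vessel_is_fg) vals_line else !vals_line
  # majority-of-3 filter along the line: single-pixel class flips at the
  # lumen edges would otherwise extend or split the vessel run
  if (length(on_vessel) >= 3L)
    on_vessel <- stats::runmed(as.numeric(on_vessel), 3L) >= 0.5
  bfi_line <- bfi_map[cbind(px[, "row"], px[, "col"])]
  # BFI over the interior of the longest vessel run: pixels within the
  # contrast-window radius of the run edges carry partial-volume contrast
  # and would dilute the vessel BFI, so they are eroded away when possible.
  r <- rle(on_vessel)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs)) {
    best <- runs[which.max(r$lengths[runs])]
    len <- r$lengths[best]
    er <- min(3L, (len - 1L) %/% 2L)
    sel_in <- (starts[best] + er):(ends[best] - er)
    bfi_vessel <- mean(bfi_line[sel_in])
    d_um <- len * um_per_pixel
    # guard against a vanished vessel: when the "vessel" class is not
    # clearly brighter or darker than the rest of the crop, the crop has no
    # segmentable vessel (complete occlusion) and the diameter is zero
    crop_bfi <- crop_rect(bfi_map, roi$window)$vals
    fg_crop <- cr$vals > thr
    other_px <- crop_bfi[fg_crop != vessel_is_fg]
    other <- if (length(other_px)) mean(other_px) else bfi_vessel
    ratio <- max(bfi_vessel, other) / max(min(bfi_vessel, other),
                                          .Machine$double.eps)
    if (!is.finite(ratio) || ratio < min_contrast) d_um <- 0
  } else {
    bfi_vessel <- mean(bfi_line)
    d_um <- 0
  }
  list(diameter_um = d_um, bfi = bfi_vessel)
}

# Box variant of measure_roi_frame for the real-time controller: the light
# spot is a 2-D region, so the diameter is the median vessel-run length over
# all window rows and the BFI pools the eroded run interiors of every row.
# Much lower variance than a single section line, which matters when each
# estimate comes from one frame of spatial contrast.
measure_roi_box <- function(bfi_map, roi, um_per_pixel, min_contrast = 2.2) {
  crop_bfi <- crop_rect(bfi_map, roi$window)$vals
  dom <- 1 / pmax(crop_bfi, .Machine$double.eps)
  thr <- tryCatch(otsu_threshold(dom), error = function(e) NA_real_)
  if (is.na(thr)) return(list(diameter_um = 0, bfi = mean(crop_bfi)))
  fg <- dom > thr
  ctr_rows <- unique(pmin(pmax(nrow(fg) %/% 2L + (-1L:1L), 1L), nrow(fg)))
  ctr_cols <- unique(pmin(pmax(ncol(fg) %/% 2L + (-1L:1L), 1L), ncol(fg)))
  vessel_is_fg <- mean(fg[ctr_rows, ctr_cols]) >= 0.5
  on_vessel <- if (vessel_is_fg) fg else !fg
  # majority-of-3 along each row, vectorized over the whole crop
  nc_ <- ncol(on_vessel)
  m <- on_vessel * 1L
  maj <- m[, c(1L, seq_len(nc_ - 1L)), drop = FALSE] + m +
    m[, c(seq_len(nc_ - 1L) + 1L, nc_), drop = FALSE]
  on_vessel <- maj >= 2L
  runs <- integer(nrow(fg)); interior <- numeric(0)
  for (i in seq_len(nrow(fg))) {
    r <- rle(on_vessel[i, ])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    w <- which(r$values)
    if (!length(w)) next
    b <- w[which.max(r$lengths[w])]
    runs[i] <- r$lengths[b]
    er <- min(3L, (runs[i] - 1L) %/% 2L)
    interior <- c(interior, crop_bfi[i, (starts[b] + er):(ends[b] - er)])
  }
  d_um <- mean(runs) * um_per_pixel  # mean across rows: sub-pixel stability
  bfi_vessel <- if (length(interior)) mean(interior) else mean(crop_bfi)
  other_px <- crop_bfi[fg != vessel_is_fg]
  other <- if (length(other_px)) mean(other_px) else bfi_vessel
  ratio <- max(bfi_vessel, other) / max(min(bfi_vessel, other),
                                        .Machine$double.eps)
  if (!is.finite(ratio) || ratio < min_contrast) d_um <- 0
  list(diameter_um = d_um, bfi = bfi_vessel)
}

#' Vessel diameter and blood-flow traces over five adjacent ROIs
#'
#' For every frame and ROI: per-frame Otsu binarization of the ROI window,
#' diameter as the longest vessel run on the section line, line-mean BFI
#' over the vessel class, and `BF = pi D^2/4 * BFI`. Traces are normalized
#' to the baseline window; following the complete-occlusion convention, the
#' diameter is set to zero on frames whose relative blood flow falls below
#' `occlusion_threshold`.
#'
#' @param bfi_series a `bfi_series` (absolute, not yet normalized).
#' @param rois list of ROIs, each `list(line = ..., window = ...)` in 0-based
#'   JSON convention (see [synth_geometry()]); typically 5.
#' @param baseline_window `c(t0, t1)` seconds, before light onset.
#' @param um_per_pixel microns per pixel.
#' @param occlusion_threshold relative-BF level defining complete occlusion.
#' @return object of class `hemo_trace`: list with `summary` (data.frame:
#'   `time_s`, `d_um`, `d_sd`, `bf`, `bf_sd`, `rel_d`, `rel_bf`), `per_roi`
#'   (long data.frame), `baseline` (per-ROI baseline D and BF).
#' @export
vessel_trace <- function(bfi_series, rois, baseline_window, um_per_pixel,
                         occlusion_threshold = 0.10, min_contrast = 2.2) {
  stopifnot(inherits(bfi_series, "bfi_series"))
  tt <- bfi_series$frame_times
  nT <- length(tt); nR <- length(rois)
  d_mat <- matrix(0, nT, nR); bfi_mat <- matrix(0, nT, nR)
  for (i in seq_len(nT)) {
    map <- bfi_series$bfi[, , i]
    dom <- 1 / pmax(map, .Machine$double.eps)
    for (j in seq_len(nR)) {
      m <- measure_roi_frame(map, rois[[j]], um_per_pixel, min_contrast,
                             dom = dom)
      d_mat[i, j] <- m$diameter_um
      bfi_mat[i, j] <- m$bfi
    }
  }
  bf_mat <- pi * d_mat^2 / 4 * bfi_mat
  in_base <- tt >= baseline_window[1L] & tt <= baseline_window[2L]
  if (!any(in_base)) stop("baseline window contains no frames")
  d_base <- colMeans(d_mat[in_base, , drop = FALSE])
  bf_base <- colMeans(bf_mat[in_base, , drop = FALSE])
  if (any(d_base <= 0))
    stop("an ROI has zero diameter during baseline (off-vessel ROI)")
  rel_d_mat <- sweep(d_mat, 2L, d_base, "/")
  rel_bf_mat <- sweep(bf_mat, 2L, bf_base, "/")
  occluded <- rel_bf_mat < occlusion_threshold
  d_mat[occluded] <- 0
  rel_d_mat[occluded] <- 0

  summary <- data.frame(
    time_s = tt,
    d_um = rowMeans(d_mat),
    d_sd = apply(d_mat, 1L, stats::sd),
    bf = rowMeans(bf_mat),
    bf_sd = apply(bf_mat, 1L, stats::sd),
    rel_d = rowMeans(rel_d_mat),
    rel_bf = rowMeans(rel_bf_mat))
  per_roi <- data.frame(
    time_s = rep(tt, nR),
    roi_id = rep(seq_len(nR), each = nT),
    diameter_um = as.vector(d_mat),
    bfi_vessel = as.vector(bfi_mat),
    blood_flow = as.vector(bf_mat),
    rel_d = as.vector(rel_d_mat),
    rel_bf = as.vector(rel_bf_mat))
  structure(list(summary = summary, per_roi = per_roi,
                 baseline = data.frame(roi_id = seq_len(nR), d_um = d_base,
                                       bf = bf_base),
                 occlusion_threshold = occlusion_threshold),
            class = "hemo_trace")
}

#' @export
print.hemo_trace <- function(x, ...) {
  cat("<hemo_trace>", nrow(x$summary), "frames,",
      nrow(x$baseline), "ROIs\n")
  cat(sprintf("  baseline D = %.1f um, BF = %.3g a.u.um^2\n",
              mean(x$baseline$d_um), mean(x$baseline$bf)))
  invisible(x)
}
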