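# Cortical ischemia classification, spreading depression, correlation maps.

#' Classify cortical ischemia severity from a relative-BFI map
#'
#' Classes on the relative BFI (1 = baseline): `normal` >= 0.8 (within 20%
#' of baseline), `benign` in [0.4, 0.8), `penumbra` in [0.2, 0.4), `infarct`
#' < 0.2. Intervals are half-open with the more severe class winning the
#' shared endpoint; pixels outside the mask are `outside`.
#'
#' @param rel_map H x W matrix of relative BFI (>= 0).
#' @param mask logical cortex mask (non-empty).
#' @param thresholds named vector `c(normal = 0.8, benign = 0.4,
#'   penumbra = 0.2)` giving the lower bound of each class.
#' @return object of class `ischemia_labels`: list with `labels` (character
#'   matrix), `fractions` (named, sums to 1 over the mask), `thresholds`.
#' @export
classify_ischemia <- function(rel_map, mask,
                              thresholds = c(normal = 0.8, benign = 0.4,
                                             penumbra = 0.2)) {
  if (!any(mask)) stop("cortex mask is empty")
  if (any(rel_map < 0)) stop("relative BFI must be non-negative")
  labels <- matrix("outside", nrow(rel_map), ncol(rel_map))
  v <- rel_map[mask]
  cls <- ifelse(v >= thresholds["normal"], "normal",
         ifelse(v >= thresholds["benign"], "benign",
         ifelse(v >= thresholds["penumbra"], "penumbra", "infarct")))
  labels[mask] <- cls
  fr <- vapply(c("normal", "benign", "penumbra", "infarct"),
               function(k) mean(cls == k), numeric(1))
  structure(list(labels = labels, fractions = fr, thresholds = thresholds),
            class = "ischemia_labels")
}

#' Per-class cortical area fractions over time
#'
#' @param rel_series a relative `bfi_series` (see [relative_bfi_series()]) or
#'   a bare H x W x T array of relative BFI.
#' @param mask logical cortex mask.
#' @param thresholds as in [classify_ischemia()].
#' @return data.frame with `time_s` and one column per class; rows sum to 1.
#' @export
area_fraction_series <- function(rel_series, mask,
                                 thresholds = c(normal = 0.8, benign = 0.4,
                                                penumbra = 0.2)) {
  if (inherits(rel_series, "bfi_series")) {
    arr <- rel_series$bfi; tt <- rel_series$frame_times
  } else {
    arr <- rel_series; tt <- seq_len(dim(arr)[3L]) - 1
  }
  d <- dim(arr)
  flat <- matrix(arr, d[1L] * d[2L], d[3L])[as.vector(mask), , drop = FALSE]
  brk <- c(-Inf, thresholds[c("penumbra", "benign", "normal")], Inf)
  out <- t(apply(flat, 2L, function(v) {
    tabulate(findInterval(v, brk), nbins = 4L) / length(v)
  }))
  data.frame(time_s = tt, infarct = out[, 1L], penumbra = out[, 2L],
             benign = out[, 3L], normal = out[, 4L])
}

# Sub-sample refinement of a trough on a detrended trace (background ~ 1):
# squared-deficit centroid over +/- halfwidth_s of the discrete minimum,
# iterated once to re-centre the window. Unbiased for symmetric troughs and
# far more noise-robust than a local parabola.
refine_trough <- function(time_s, x, i, halfwidth_s = 5) {
  centre <- time_s[i]
  for (pass in 1:2) {
    sel <- which(abs(time_s - centre) <= halfwidth_s)
    if (length(sel) < 5L) return(centre)
    d <- pmax(1 - x[sel], 0)^2
    if (sum(d) <= 0) return(centre)
    centre <- sum(d * time_s[sel]) / sum(d)
  }
  centre
}

find_troughs <- function(time_s, x, depth, recover, window_s, smooth_k,
                         detrend_s = 30) {
  # transient troughs ride on a slowly drifting ischemic background; divide
  # by a long running median so the depth criterion sees only the transient
  dt <- stats::median(diff(time_s))
  k_det <- round(detrend_s / dt)
  if (k_det %% 2L == 0L) k_det <- k_det + 1L
  if (is.finite(k_det) && k_det >= 3L && k_det < length(x)) {
    base <- stats::runmed(x, k_det, endrule = "median")
    x <- x / pmax(base, .Machine$double.eps)
  } else {
    x <- x / max(stats::median(x), .Machine$double.eps)
  }
  xs <- moving_median(x, smooth_k)
  n <- length(xs)
  troughs <- data.frame(time_s = numeric(0), value = numeric(0))
  i <- 2L
  while (i < n) {
    if (xs[i] <= xs[i - 1L] && xs[i] < xs[i + 1L] && xs[i] < 1 - depth) {
      upto <- which(time_s > time_s[i] & time_s <= time_s[i] + window_s)
      if (length(upto) && any(xs[upto] >= xs[i] + recover)) {
        troughs <- rbind(troughs, data.frame(
          time_s = refine_trough(time_s, xs, i), value = xs[i]))
        nxt <- upto[which(xs[upto] >= xs[i] + recover)[1L]]
        i <- nxt
        next
      }
    }
    i <- i + 1L
  }
  troughs
}

#' Detect spreading-depression events from ordered cortical ROI traces
#'
#' An SD event is a transient trough (local minimum below `1 - depth` that
#' recovers by at least `recover` within `window_s`) appearing in at least
#' three consecutive, spatially ordered ROIs with strictly increasing trough
#' times. Trough times are refined by parabolic interpolation; the
#' propagation speed is estimated from the ROI spacing when supplied.
#'
#' @param roi_traces list (ordered along the propagation axis) of data.frames
#'   (`time_s`, `value`): relative BFI, typically restricted to the
#'   occlusion window. Traces are detrended internally by a running median
#'   so a slowly drifting ischemic background does not mask the transient.
#' @param depth fractional trough depth threshold (default 0.15).
#' @param recover required recovery (default 0.08).
#' @param window_s recovery window in seconds (default 60).
#' @param smooth_k moving-median window (default 5).
#' @param detrend_s running-median detrending window, seconds (default 30).
#' @param spacing_um ROI centre spacing in microns (optional, for speed).
#' @return object of class `sd_events`: list with `events` (list of
#'   data.frames of per-ROI trough times), `count`, `speed_um_s` (`NA`
#'   without spacing), `troughs` per ROI.
#' @export
detect_sd <- function(roi_traces, depth = 0.15, recover = 0.08,
                      window_s = 60, smooth_k = 5, detrend_s = 30,
                      spacing_um = NULL) {
  if (length(roi_traces) < 3L) stop("need at least 3 ROIs")
  troughs <- lapply(roi_traces, function(df) {
    find_troughs(df$time_s, df$value, depth, recover, window_s, smooth_k,
                 detrend_s)
  })
  # greedy chaining: walk ROIs in order, extending runs of strictly
  # increasing trough times
  events <- list()
  used <- lapply(troughs, function(tr) rep(FALSE, nrow(tr)))
  n_roi <- length(troughs)
  for (start in seq_len(n_roi - 2L)) {
    tr0 <- troughs[[start]]
    for (k in seq_len(nrow(tr0))) {
      if (used[[start]][k]) next
      chain <- data.frame(roi = start, time_s = tr0$time_s[k],
                          idx = k)
      t_prev <- tr0$time_s[k]
      for (j in (start + 1L):n_roi) {
        trj <- troughs[[j]]
        cand <- which(!used[[j]] & trj$time_s > t_prev)
        if (!length(cand)) break
        b <- cand[which.min(trj$time_s[cand])]
        chain <- rbind(chain, data.frame(roi = j, time_s = trj$time_s[b],
                                         idx = b))
        t_prev <- trj$time_s[b]
      }
      if (nrow(chain) >= 3L) {
        for (r in seq_len(nrow(chain)))
          used[[chain$roi[r]]][chain$idx[r]] <- TRUE
        events[[length(events) + 1L]] <- chain[, c("roi", "time_s")]
      }
    }
  }
  speed <- NA_real_
  if (length(events) && !is.null(spacing_um)) {
    ch <- events[[1L]]
    fit <- stats::lm(time_s ~ roi, data = ch)
    slope <- unname(stats::coef(fit)[2L])
    if (is.finite(slope) && slope > 0) speed <- spacing_um / slope
  }
  structure(list(events = events, count = length(events),
                 speed_um_s = speed, troughs = troughs),
            class = "sd_events")
}

#' Pixelwise Pearson correlation map against a reference trace
#'
#' Computes `r = cov(X, Y) / (sd(X) sd(Y))` between a reference trace (the
#' relative diameter or blood flow of the main vessel) and each pixel's
#' relative-BFI time course. Zero-variance pixels are flagged undefined
#' (`NA`) and excluded from the strong-area denominator.
#'
#' @param reference data.frame (`time_s`, `value`) or numeric vector aligned
#'   with the series frames (>= 10 samples).
#' @param rel_series relative `bfi_series` or bare H x W x T array.
#' @param mask logical mask over which fractions are computed (hemisphere).
#' @param strong_threshold correlation defining strongly correlated areas
#'   (default 0.5).
#' @param extra_masks optional named list of masks for per-region mean r.
#' @return object of class `correlation_map`: list with `r` (matrix, `NA`
#'   where undefined), `strong_fraction`, `mean_r` (over defined mask
#'   pixels), `region_means`.
#' @export
correlation_map <- function(reference, rel_series, mask,
                            strong_threshold = 0.5, extra_masks = list()) {
  if (inherits(rel_series, "bfi_series")) {
    arr <- rel_series$bfi; tt <- rel_series$frame_times
  } else {
    arr <- rel_series; tt <- NULL
  }
  ref <- if (is.data.frame(reference)) {
    if (!is.null(tt) &&
        (nrow(reference) != dim(arr)[3L] ||
         max(abs(reference$time_s - tt)) > 1e-6))
      stop("reference and series must share timestamps")
    reference$value
  } else as.numeric(reference)
  nT <- dim(arr)[3L]
  if (length(ref) != nT) stop("reference length must match frame count")
  if (nT < 10L) stop("need at least 10 samples")
  d <- dim(arr)
  flat <- matrix(arr, d[1L] * d[2L], nT)
  xc <- ref - mean(ref)
  sx <- sqrt(sum(xc^2))
  mu <- rowMeans(flat)
  yc <- flat - mu
  sy <- sqrt(rowSums(yc^2))
  num <- as.vector(yc %*% xc)
  r <- rep(NA_real_, length(num))
  ok <- sy > 0 & sx > 0
  r[ok] <- num[ok] / (sx * sy[ok])
  r_mat <- matrix(r, d[1L], d[2L])
  in_mask <- as.vector(mask)
  defined <- in_mask & ok
  strong_fraction <- if (any(defined))
    sum(r[defined] > strong_threshold) / sum(defined) else NA_real_
  region_means <- vapply(extra_masks, function(m) {
    sel <- as.vector(m) & ok
    if (any(sel)) mean(r[sel]) else NA_real_
  }, numeric(1))
  structure(list(r = r_mat, strong_fraction = strong_fraction,
                 mean_r = if (any(defined)) mean(r[defined]) else NA_real_,
                 region_means = region_means,
                 strong_threshold = strong_threshold,
                 n_undefined = sum(in_mask & !ok)),
            class = "correlation_map")
}
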