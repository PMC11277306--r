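#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pad a matrix by edge replication
#'
#' @param m numeric matrix.
#' @param r non-negative integer pad radius (rows and columns).
#' @return a `(nrow+2r) x (ncol+2r)` matrix.
#' @keywords internal
pad_replicate <- function(m, r) {
  if (r == 0L) return(m)
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

#' Box sum over a (2r+1)^2 window with edge replication
#'
#' Summed-area-table implementation; O(HW) per call.
#'
#' @param m numeric matrix.
#' @param r window radius.
#' @return matrix of the same size as `m`; entry (i,j) is the sum of `m`
#'   over the replicated (2r+1)x(2r+1) window centred at (i,j).
#' @keywords internal
box_sum <- function(m, r) {
  if (r == 0L) return(m)
  p <- pad_replicate(m, r)
  # summed area table with a zero border row/column
  s <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  n <- nrow(m); k <- 2L * r + 1L
  i1 <- seq_len(n); j1 <- seq_len(ncol(m))
  s[i1 + k, j1 + k, drop = FALSE] - s[i1, j1 + k, drop = FALSE] -
    s[i1 + k, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
}

#' Rasterize a straight line segment onto the pixel grid
#'
#' Coordinates follow the package's JSON convention: 0-based pixel indices,
#' `x` = column, `y` = row. The segment is sampled at
#' `max(|dx|, |dy|) + 1` evenly spaced points and rounded.
#'
#' @param line list or numeric vector with `x0, y0, x1, y1` (0-based).
#' @param dim image dimensions `c(nrow, ncol)`; points outside raise an error.
#' @return integer matrix with columns `row`, `col` (1-based).
#' @export
raster_line <- function(line, dim) {
  v <- unlist(line[c("x0", "y0", "x1", "y1")])
  if (length(v) != 4L || anyNA(v)) stop("line must supply x0, y0, x1, y1")
  n <- max(abs(v["x1"] - v["x0"]), abs(v["y1"] - v["y0"])) + 1L
  xs <- round(seq(v["x0"], v["x1"], length.out = n)) + 1L
  ys <- round(seq(v["y0"], v["y1"], length.out = n)) + 1L
  if (any(ys < 1L | ys > dim[1L] | xs < 1L | xs > dim[2L]))
    stop("section line extends outside the image")
  cbind(row = as.integer(ys), col = as.integer(xs))
}

#' Longest run of TRUE in a logical vector
#' @keywords internal
longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Centred moving median (odd window), edges shrunk symmetrically
#' @keywords internal
moving_median <- function(x, k = 5L) {
  if (k <= 1L || length(x) < 3L) return(x)
  k <- min(k, length(x) - (1L - length(x) %% 2L))
  if (k %% 2L == 0L) k <- k - 1L
  if (k <= 1L) return(x)
  stats::runmed(x, k, endrule = "median")
}

#' First time a condition is sustained for a minimum duration
#'
#' Works on non-uniform timestamps: the onset is the first flagged sample
#' `t[i]` such that at least `frac` of the samples in `[t[i], t[i] + min_dur]`
#' are flagged and the window is fully covered by the trace (or the trace
#' ends flagged). `frac = 1` demands strictly consecutive samples; the
#' default 0.9 tolerates isolated dropouts near the threshold, which removes
#' the one-sided detection delay a strictly-consecutive rule incurs on noisy
#' traces while still rejecting single-frame excursions.
#'
#' @param time numeric timestamps (strictly increasing), seconds.
#' @param flag logical vector, same length.
#' @param min_dur minimum sustained duration in seconds.
#' @param frac minimum fraction of flagged samples inside the window.
#' @return the timestamp starting the first qualifying run, or `NA_real_`.
#' @keywords internal
sustained_onset <- function(time, flag, min_dur, frac = 0.9) {
  stopifnot(length(time) == length(flag))
  flag[is.na(flag)] <- FALSE
  n <- length(flag)
  if (!any(flag)) return(NA_real_)
  cnt <- cumsum(flag)
  ends <- findInterval(time + min_dur, time)
  for (i in which(flag)) {
    j <- max(ends[i], i)
    if (time[j] - time[i] < min_dur - 1e-9) next  # insufficient coverage
    got <- cnt[j] - cnt[i] + 1L
    if (got / (j - i + 1L) >= frac) return(time[i])
  }
  NA_real_
}

#' Quadrant swap so the DC component sits at the centre pixel
#' @param m matrix (typically a focal-plane field or intensity map).
#' @return matrix with indices rolled by `floor(dim/2)`.
#' @export
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c(seq(floor(h / 2) + 1L, h), seq_len(floor(h / 2))),
    c(seq(floor(w / 2) + 1L, w), seq_len(floor(w / 2))), drop = FALSE]
}

#' Inverse of [fftshift2()]
#' @param m matrix.
#' @export
ifftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c(seq(h - floor(h / 2) + 1L, h), seq_len(h - floor(h / 2))),
    c(seq(w - floor(w / 2) + 1L, w), seq_len(w - floor(w / 2))),
    drop = FALSE]
}

#' Linear interpolation of a trace at an arbitrary time
#' @keywords internal
interp_at <- function(time, x, t0) {
  stats::approx(time, x, xout = t0, rule = 2)$y
}
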