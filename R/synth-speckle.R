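# Speckle rendering: flow -> raw camera frames.

#' Render raw speckle frames from a relative-flow movie
#'
#' Local speckle contrast is controlled by averaging `N` independent fully
#' developed speckle realizations per pixel, with `N = round(1 + g * flow)`,
#' so the expected contrast is `K = 1 / sqrt(N)`. The per-pixel mean of `N`
#' independent unit-mean exponential intensities is distributed
#' `Gamma(shape = N, rate = N)` and is sampled as such (one draw per pixel).
#' Detector counts are `mean_counts * intensity + dark_offset` plus Gaussian
#' shot noise with sd `shot_scale * sqrt(counts)`, quantized to the
#' configured bit depth.
#'
#' @param flow H x W x T array of relative flow (>= 0), or a single matrix.
#' @param cfg a [synth_config()]; `cfg$speckle` and `cfg$noise` control the
#'   encoding; timestamps come from `cfg$rate_schedule` unless supplied.
#' @param timestamps optional per-frame timestamps (seconds).
#' @param seed optional seed; default `cfg$seed + 1`, so the flow generator
#'   and the renderer use distinct streams.
#' @return a `speckle_stack`: list with integer `frames` (H x W x T array of
#'   counts), `timestamps`, `exposure_time_ms`, `um_per_pixel`, `bit_depth`.
#' @export
render_speckle <- function(flow, cfg, timestamps = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.matrix(flow)) flow <- array(flow, dim = c(dim(flow), 1L))
  if (any(flow < 0)) stop("flow values must be non-negative")
  set.seed(seed %||% (cfg$seed + 1L))
  sp <- cfg$speckle; nz <- cfg$noise
  n_avg <- round(1 + sp$g * flow)
  n <- length(n_avg)
  intensity <- stats::rgamma(n, shape = n_avg, rate = n_avg)
  counts <- sp$mean_counts * intensity
  if (nz$shot_scale > 0)
    counts <- counts + stats::rnorm(n, 0, nz$shot_scale * sqrt(pmax(counts, 1)))
  counts <- counts + nz$dark_offset
  cap <- 2^sp$bit_depth - 1
  frames <- array(pmin(pmax(round(counts), 0), cap), dim = dim(flow))
  if (is.null(timestamps))
    timestamps <- schedule_timestamps(cfg$rate_schedule, cfg$duration_s)
  timestamps <- timestamps[seq_len(dim(flow)[3L])]
  speckle_stack(frames, timestamps, cfg$exposure_time_ms, cfg$um_per_pixel,
                sp$bit_depth)
}

#' Construct a speckle stack object
#'
#' The raw input of the analysis pipeline: a T-frame grayscale stack with
#' acquisition metadata.
#'
#' @param frames H x W x T numeric array.
#' @param timestamps strictly increasing per-frame times, seconds.
#' @param exposure_time_ms exposure time (metadata).
#' @param um_per_pixel microns per pixel.
#' @param bit_depth sensor bit depth (8 or 16).
#' @return object of class `speckle_stack`.
#' @export
speckle_stack <- function(frames, timestamps, exposure_time_ms = 10,
                          um_per_pixel = 10, bit_depth = 16L) {
  if (length(dim(frames)) != 3L) stop("frames must be an H x W x T array")
  if (length(timestamps) != dim(frames)[3L])
    stop("one timestamp per frame required")
  if (any(diff(timestamps) <= 0)) stop("timestamps must strictly increase")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 exposure_time_ms = exposure_time_ms,
                 um_per_pixel = um_per_pixel, bit_depth = as.integer(bit_depth)),
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<speckle_stack> %d x %d px, %d frames, %.1f-%.1f s, %d-bit\n",
              d[1], d[2], d[3], x$timestamps[1], x$timestamps[d[3]],
              x$bit_depth))
  invisible(x)
}

#' Synthesize a relative-BFI stack with prescribed pixelwise correlation
#'
#' Builds a T-frame series in which each pixel's time course has Pearson
#' correlation approximately `r_target` with the supplied reference trace:
#' `x = r * z_ref + sqrt(1 - r^2) * noise` on standardized scales. Used to
#' validate correlation-map recovery.
#'
#' @param reference numeric reference trace (length T).
#' @param r_target H x W matrix of target correlations in `[-1, 1]`.
#' @param seed RNG seed.
#' @return H x W x T array.
#' @export
make_correlated_stack <- function(reference, r_target, seed = 1L) {
  if (any(abs(r_target) > 1)) stop("r_target must lie in [-1, 1]")
  set.seed(seed)
  nT <- length(reference)
  z <- as.numeric(scale(reference))
  h <- nrow(r_target); w <- ncol(r_target)
  out <- array(0, dim = c(h, w, nT))
  noise <- array(stats::rnorm(h * w * nT), dim = c(h, w, nT))
  for (t in seq_len(nT))
    out[, , t] <- r_target * z[t] + sqrt(1 - r_target^2) * noise[, , t]
  out
}
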