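# Weighted Gerchberg-Saxton (GSW) hologram design for SLM spot targeting.
#
# Scalar Fourier-optics model: the SLM plane carries a unit-amplitude field
# with phase phi; the focal (target) plane is its unitary 2-D FFT, displayed
# fftshift-ed so DC sits at the centre pixel. Parseval holds exactly.

#' Rasterize target spots into a binary map
#'
#' Spots are rectangles specified in microns in the focal plane, centred on
#' the field centre (offsets in microns), with optional rotation. A pixel
#' belongs to a spot when its centre falls inside the rotated rectangle
#' (half-open on the max side, so a 50 x 250 um spot at 5 um/px is exactly
#' 10 x 50 px).
#'
#' @param spot_specs list of spots, each
#'   `list(center_um = c(x, y), width_um, height_um, angle_deg = 0)`.
#' @param field_px field size in pixels `c(nrow, ncol)`.
#' @param um_per_pixel focal-plane sampling.
#' @return integer matrix: 0 = background, `k` = index of spot `k` (also
#'   usable as a binary map); spots out of bounds raise an error.
#' @export
make_target <- function(spot_specs, field_px, um_per_pixel) {
  nr <- field_px[1L]; nc <- field_px[2L]
  target <- matrix(0L, nr, nc)
  cy0 <- floor(nr / 2) + 1L; cx0 <- floor(nc / 2) + 1L
  xs <- (col(target) - cx0) * um_per_pixel
  ys <- (row(target) - cy0) * um_per_pixel
  for (k in seq_along(spot_specs)) {
    s <- spot_specs[[k]]
    ang <- (s$angle_deg %||% 0) * pi / 180
    ca <- cos(ang); sa <- sin(ang)
    if (abs(ca) < 1e-12) ca <- 0
    if (abs(sa) < 1e-12) sa <- 0
    dx <- xs - s$center_um[1L]; dy <- ys - s$center_um[2L]
    u <- ca * dx + sa * dy
    v <- -sa * dx + ca * dy
    inside <- u >= -s$width_um / 2 & u < s$width_um / 2 &
      v >= -s$height_um / 2 & v < s$height_um / 2
    # bounds check on the unrotated extent
    half <- (abs(s$center_um) + c(s$width_um, s$height_um) / 2 +
               abs(sin(ang)) * c(s$height_um, s$width_um) / 2)
    if (half[1L] > nc / 2 * um_per_pixel || half[2L] > nr / 2 * um_per_pixel)
      stop("spot ", k, " extends outside the field of view")
    if (!any(inside)) stop("spot ", k, " rasterizes to zero pixels")
    target[inside] <- k
  }
  target
}

fft2_unitary <- function(z, inverse = FALSE) {
  stats::fft(z, inverse = inverse) / sqrt(length(z))
}

#' Focal-plane intensity of an SLM phase map
#'
#' `I = |FFT(exp(i phase))|^2` (unitary transform, fftshift-ed so DC is at
#' the centre), normalized to total power 1. Optionally zeroes a central
#' disk emulating the physical zero-order block.
#'
#' @param phase H x W phase map in radians.
#' @param block_radius_px radius of the zero-order block (0 = no block).
#' @return intensity matrix summing to 1 (before blocking).
#' @export
reconstruct <- function(phase, block_radius_px = 0) {
  field <- fft2_unitary(exp(1i * phase))
  intensity <- fftshift2(Mod(field)^2)
  intensity <- intensity / sum(intensity)
  if (block_radius_px > 0) {
    cy <- floor(nrow(phase) / 2) + 1L; cx <- floor(ncol(phase) / 2) + 1L
    d2 <- (row(intensity) - cy)^2 + (col(intensity) - cx)^2
    intensity[d2 <= block_radius_px^2] <- 0
  }
  intensity
}

#' Weighted Gerchberg-Saxton phase retrieval for spot targets
#'
#' Iterates: forward-transform the unit-amplitude SLM field; update per-spot
#' weights `w <- w * mean(a_spots) / a_spot` from the mean focal amplitude
#' over each spot; impose the weighted target amplitude on the spots (zero
#' elsewhere) while retaining the focal phase; back-transform and keep only
#' the phase. Reconstruction metrics are computed from a final forward
#' transform.
#'
#' @param target integer/logical matrix from [make_target()] (spot labels or
#'   a binary map, non-empty).
#' @param n_iter iterations (>= 1, default 30).
#' @param seed seed for the random initial phase.
#' @param block_radius_px zero-order block radius used in the efficiency
#'   metric (default 0).
#' @return object of class `hologram_plan`: `phase` (radians in [0, 2*pi)),
#'   `target`, `efficiency` (power fraction inside the target),
#'   `uniformity` (1 - (max-min)/(max+min) over per-spot mean intensities),
#'   `intensity`, `iterations`.
#' @export
gsw_phase <- function(target, n_iter = 30L, seed = 1L, block_radius_px = 0) {
  if (!any(target > 0)) stop("target is empty")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  labels <- sort(unique(target[target > 0]))
  spot_idx <- lapply(labels, function(l) which(target == l))
  tgt_idx <- which(target > 0)
  set.seed(seed)
  phase <- matrix(stats::runif(length(target), 0, 2 * pi),
                  nrow(target), ncol(target))
  w <- rep(1, length(labels))
  amp_des <- sqrt(1 / length(tgt_idx))
  for (it in seq_len(n_iter)) {
    focal <- fftshift2(fft2_unitary(exp(1i * phase)))
    a_spot <- vapply(spot_idx, function(ix) mean(Mod(focal[ix])), numeric(1))
    w <- w * mean(a_spot) / pmax(a_spot, .Machine$double.eps)
    amp <- matrix(0, nrow(target), ncol(target))
    for (j in seq_along(labels)) amp[spot_idx[[j]]] <- amp_des * w[j]
    constrained <- amp * exp(1i * Arg(focal))
    back <- fft2_unitary(ifftshift2(constrained), inverse = TRUE)
    phase <- Arg(back) %% (2 * pi)
  }
  intensity <- reconstruct(phase, block_radius_px = block_radius_px)
  eff <- sum(intensity[tgt_idx])
  spot_mean <- vapply(spot_idx, function(ix) mean(intensity[ix]), numeric(1))
  unif <- if (length(spot_mean) > 1L)
    1 - (max(spot_mean) - min(spot_mean)) /
      (max(spot_mean) + min(spot_mean))
  else 1
  structure(list(phase = phase, target = target, efficiency = eff,
                 uniformity = unif, intensity = intensity,
                 iterations = n_iter, weights = w),
            class = "hologram_plan")
}

#' @export
print.hologram_plan <- function(x, ...) {
  cat(sprintf(
    "<hologram_plan> %d x %d px, %d spots, %d iters, eff %.1f%%, unif %.2f\n",
    nrow(x$phase), ncol(x$phase), length(unique(x$target[x$target > 0])),
    x$iterations, 100 * x$efficiency, x$uniformity))
  invisible(x)
}
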