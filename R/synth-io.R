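# Fixture round-trip: multi-page TIFF + JSON ground truth + YAML config.

#' Write a synthetic recording to disk
#'
#' Writes `stack.tif` (multi-page grayscale TIFF at the stack's bit depth),
#' `stack_meta.json` (timestamps and acquisition metadata), `truth.json`
#' (events, traces, masks) and `config.yaml`. The round trip through
#' [read_fixture()] is lossless.
#'
#' @param stack a `speckle_stack`.
#' @param truth a `ground_truth` (optional, may be `NULL`).
#' @param dir existing output directory; a missing directory is an error and
#'   nothing is written.
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(stack, truth, dir) {
  stopifnot(inherits(stack, "speckle_stack"))
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  cap <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$frames)[3L]),
                  function(i) stack$frames[, , i] / cap)
  f_tif <- file.path(dir, "stack.tif")
  tiff::writeTIFF(pages, f_tif, bits.per.sample = stack$bit_depth,
                  compression = "none", reduce = FALSE)
  meta <- list(timestamps_s = stack$timestamps,
               exposure_time_ms = stack$exposure_time_ms,
               um_per_pixel = stack$um_per_pixel,
               bit_depth = stack$bit_depth)
  f_meta <- file.path(dir, "stack_meta.json")
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA)
  written <- c(f_tif, f_meta)
  if (!is.null(truth)) {
    f_truth <- file.path(dir, "truth.json")
    jsonlite::write_json(truth_to_list(truth), f_truth, auto_unbox = TRUE,
                         digits = NA)
    f_cfg <- file.path(dir, "config.yaml")
    yaml::write_yaml(unclass(truth$config), f_cfg)
    written <- c(written, f_truth, f_cfg)
  }
  invisible(written)
}

truth_to_list <- function(truth) {
  list(seed = truth$seed,
       time_s = truth$time_s,
       traces = as.list(truth$traces),
       events = truth$events,
       region_masks = lapply(truth$region_masks, function(m) m * 1L),
       collateral_roi = truth$collateral_roi * 1L,
       sd_rois = lapply(truth$sd_rois, function(m) m * 1L),
       sd_spacing_um = truth$sd_spacing_um,
       rois = truth$rois,
       design_fractions = as.list(truth$design_fractions),
       geometry = truth$geometry,
       rates = truth$rates)
}

#' Read a synthetic recording written by [write_fixture()]
#'
#' @param dir directory containing `stack.tif` and `stack_meta.json`
#'   (and optionally `truth.json` / `config.yaml`).
#' @return list with `stack` (a `speckle_stack`) and, when present, `truth`
#'   (plain list form) and `config`.
#' @export
read_fixture <- function(dir) {
  f_tif <- file.path(dir, "stack.tif")
  f_meta <- file.path(dir, "stack_meta.json")
  if (!file.exists(f_tif) || !file.exists(f_meta))
    stop("not a fixture directory: ", dir)
  meta <- jsonlite::read_json(f_meta, simplifyVector = TRUE)
  pages <- tiff::readTIFF(f_tif, all = TRUE, as.is = TRUE)
  frames <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  stack <- speckle_stack(frames, meta$timestamps_s, meta$exposure_time_ms,
                         meta$um_per_pixel, meta$bit_depth)
  out <- list(stack = stack)
  f_truth <- file.path(dir, "truth.json")
  if (file.exists(f_truth)) {
    tr <- jsonlite::read_json(f_truth, simplifyVector = TRUE)
    tr$region_masks <- lapply(tr$region_masks, function(m) m == 1L)
    tr$collateral_roi <- tr$collateral_roi == 1L
    # an unnamed list of equal-size matrices comes back as a 3-D array
    tr$sd_rois <- if (is.array(tr$sd_rois) && length(dim(tr$sd_rois)) == 3L)
      lapply(seq_len(dim(tr$sd_rois)[1L]),
             function(i) tr$sd_rois[i, , ] == 1L)
    else lapply(tr$sd_rois, function(m) m == 1L)
    out$truth <- tr
  }
  f_cfg <- file.path(dir, "config.yaml")
  if (file.exists(f_cfg)) out$config <- yaml::read_yaml(f_cfg)
  out
}
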