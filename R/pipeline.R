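# End-to-end pipeline: synth -> BFI -> vessel traces -> phases -> cortex.

#' Read a run configuration from YAML
#'
#' The file carries a `synth` block (arguments to [synth_config()]) plus
#' optional `speckle_window`, `onset_params`, `controller` and `holography`
#' blocks. Unknown top-level keys are rejected.
#'
#' @param path YAML file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("synth", "speckle_window", "onset_params", "controller",
             "holography", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic recording
#'
#' Generates a seeded synthetic recording (or accepts a prebuilt one),
#' renders speckle, estimates BFI maps via spatiotemporal contrast, extracts
#' vessel diameter/blood-flow traces over five ROIs, segments the TIA
#' phases, measures onset times, classifies cortical ischemia over time,
#' detects spreading depression and computes diameter- and flow-referenced
#' correlation maps.
#'
#' @param cfg a [synth_config()] (or a `run_config` whose `synth` block is
#'   passed to [synth_config()]).
#' @param out_dir optional directory: when supplied, traces (CSV) and the
#'   summary (JSON) are written into it.
#' @param movie optional precomputed result of [generate_flow_movie()].
#' @param window spatiotemporal contrast window.
#' @return list of class `tia_run`: `summary` (flat named list), `trace`
#'   (`hemo_trace`), `segmentation`, `onsets`, `fractions`, `sd`,
#'   `correlation` (list for `bf` and `d` references), `truth`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, movie = NULL,
                         window = c(7L, 7L, 5L)) {
  if (inherits(cfg, "run_config"))
    cfg <- do.call(synth_config, cfg$synth)
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(movie)) movie <- generate_flow_movie(cfg)
  truth <- movie$truth
  stack <- render_speckle(movie$flow, cfg)

  k <- compute_contrast(stack, window)
  bfi <- contrast_to_bfi(k)
  light_onset <- truth$events$light_onset
  base_win <- c(min(bfi$frame_times), light_onset - 1)
  if (base_win[2] <= base_win[1]) stop("baseline window is empty")

  trace <- vessel_trace(bfi, truth$rois, base_win, cfg$um_per_pixel)
  rel_bf <- data.frame(time_s = trace$summary$time_s,
                       value = trace$summary$rel_bf)
  rel_d <- data.frame(time_s = trace$summary$time_s,
                      value = trace$summary$rel_d)
  seg <- segment_phases(rel_bf, rel_d, light_onset_s = light_onset)

  rel_coll <- relative_series(bfi, base_win, truth$collateral_roi)
  onsets <- onset_times(rel_d, rel_bf, rel_coll, light_onset_s = light_onset)

  rel_all <- relative_bfi_series(bfi, base_win)
  fractions <- area_fraction_series(rel_all, truth$region_masks$cortex)

  # SD detection on the four cortical ROIs within the occlusion window
  sd_res <- NULL
  if (!is.na(seg$occlusion_onset)) {
    occ_end <- seg$occlusion_end %||% max(rel_bf$time_s)
    if (is.na(occ_end)) occ_end <- max(rel_bf$time_s)
    win <- c(seg$occlusion_onset, occ_end)
    sd_res <- tryCatch({
      roi_traces <- lapply(truth$sd_rois, function(m) {
        df <- relative_series(bfi, base_win, m)
        df[df$time_s >= win[1] & df$time_s <= win[2], ]
      })
      detect_sd(roi_traces, spacing_um = truth$sd_spacing_um)
    }, error = function(e) NULL)
  }

  hemis <- truth$region_masks$cortex
  extra <- truth$region_masks[c("mca", "aca")]
  cor_bf <- correlation_map(rel_bf, rel_all, hemis, extra_masks = extra)
  cor_d <- correlation_map(rel_d, rel_all, hemis, extra_masks = extra)

  summary <- list(
    seed = cfg$seed,
    n_frames = length(stack$timestamps),
    light_onset_s = light_onset,
    diameter_onset_s = onsets$diameter_onset,
    flow_onset_s = onsets$flow_onset,
    collateral_onset_s = onsets$collateral_onset,
    time_to_occlusion_c_s = seg$time_to_occlusion_c,
    occlusion_duration_d_s = seg$occlusion_duration_d,
    status = seg$status,
    max_benign_fraction = max(fractions$benign),
    max_penumbra_fraction = max(fractions$penumbra),
    max_infarct_fraction = max(fractions$infarct),
    benign_fraction_occlusion = {
      # robust (median) benign fraction over the occlusion phase: unlike the
      # raw maximum it is insensitive to the brief SD hypoperfusion transient
      if (is.na(seg$occlusion_onset)) NA_real_ else {
        o_end <- if (is.na(seg$occlusion_end)) max(fractions$time_s) else
          seg$occlusion_end
        sel <- fractions$time_s >= seg$occlusion_onset &
          fractions$time_s < o_end
        if (any(sel)) stats::median(fractions$benign[sel]) else NA_real_
      }
    },
    sd_count = if (is.null(sd_res)) 0L else sd_res$count,
    sd_speed_um_s = if (is.null(sd_res)) NA_real_ else sd_res$speed_um_s,
    mean_r_bf = cor_bf$mean_r,
    mean_r_d = cor_d$mean_r,
    strong_fraction_bf = cor_bf$strong_fraction,
    strong_fraction_d = cor_d$strong_fraction,
    mean_r_bf_mca = unname(cor_bf$region_means["mca"]),
    mean_r_bf_aca = unname(cor_bf$region_means["aca"]))

  if (any(vapply(summary[c("max_benign_fraction", "mean_r_bf")],
                 function(x) !is.finite(x), logical(1))))
    stop("pipeline produced non-finite summary values")

  out <- structure(list(summary = summary, trace = trace, segmentation = seg,
                        onsets = onsets, fractions = fractions, sd = sd_res,
                        correlation = list(bf = cor_bf, d = cor_d),
                        truth = truth),
                   class = "tia_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) stop("output directory does not exist")
    utils::write.csv(trace$summary, file.path(out_dir, "vessel_traces.csv"),
                     row.names = FALSE)
    utils::write.csv(fractions, file.path(out_dir, "area_fractions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}

#' @export
print.tia_run <- function(x, ...) {
  s <- x$summary
  cat("<tia_run> seed", s$seed, "-", s$n_frames, "frames\n")
  cat(sprintf("  onsets (s): diameter %.1f, flow %.1f, collateral %.1f\n",
              s$diameter_onset_s, s$flow_onset_s, s$collateral_onset_s))
  cat(sprintf("  c = %.1f s, d = %.1f s (%s)\n", s$time_to_occlusion_c_s,
              s$occlusion_duration_d_s, s$status))
  cat(sprintf("  max fractions: benign %.2f penumbra %.2f infarct %.2f\n",
              s$max_benign_fraction, s$max_penumbra_fraction,
              s$max_infarct_fraction))
  cat(sprintf("  mean r: BF %.2f vs D %.2f; strong areas %.2f vs %.2f\n",
              s$mean_r_bf, s$mean_r_d, s$strong_fraction_bf,
              s$strong_fraction_d))
  invisible(x)
}
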