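#' Configuration for the synthetic TIA speckle simulator
#'
#' Builds and validates the full parameter set of the synthetic recording:
#' geometry, acquisition schedule, photothrombosis kinetics, reperfusion
#' hyperemia, spreading-depression wave, cortical coupling, speckle encoding
#' and sensor noise. Defaults reproduce the experimental conditions the
#' simulator emulates: 10 ms exposure, 10 Hz acquisition dropping to 2 Hz
#' after 400 s, a ~100 um vessel occluding within minutes of light onset and
#' spontaneously recanalizing after roughly seven minutes with transient
#' hyperemia, a collateral vessel recruited at the onset of narrowing, and a
#' spreading-depression trough crossing the cortex at 3 mm/min.
#'
#' @param frame_size image size in pixels, `c(nrow, ncol)`.
#' @param um_per_pixel microns per pixel.
#' @param exposure_time_ms camera exposure in milliseconds (metadata only).
#' @param rate_schedule list of `c(start_s, hz)` pairs; must start at 0 and
#'   have positive, strictly increasing start times and positive rates.
#' @param duration_s total recording length, seconds.
#' @param baseline_duration_s time before illumination starts, seconds.
#' @param light list: `mode` one of `"feedback"` (illumination stops once the
#'   noise-free vessel blood flow stays below `feedback_threshold` — the
#'   generator's stand-in for the real-time imaging feedback), `"fixed"`
#'   (stops after `duration_s`... of the light, `light$duration_s`) or
#'   `"off"`; `intensity` normalized light intensity I (a.u., 1 = nominal);
#'   `feedback_lag_s` latency of the emulated feedback;
#'   `feedback_threshold` relative blood-flow threshold; `duration_s` used
#'   by `"fixed"`; `max_duration_s` safety cap in every mode.
#' @param kinetics list of thrombus-occupancy ODE parameters:
#'   `k_on` (1/s) light-driven seeding rate per unit intensity and dye,
#'   `k_auto` (1/s) autocatalytic platelet-recruitment rate,
#'   `k_off` (1/s) first-order lysis rate,
#'   `dye_level` photosensitizer level (a.u.),
#'   `persist_tau_s` decay time of the coagulation cascade after light off,
#'   `detach_frac` occupancy below which the decaying thrombus detaches,
#'   `detach_rate` (1/s) fast clearance rate after detachment,
#'   `jitter_sd` lognormal across-run variability applied to the rates.
#' @param vessel list: `d0_um` baseline diameter, `flow_gain` baseline vessel
#'   velocity in parenchyma-baseline units, `dead_zone` diameter fraction
#'   below which flux starts to fall, `flux_exponent` stenosis steepness,
#'   `velocity_cap` cap on relative vessel velocity, `center_col` 0-based
#'   column of the vessel axis (NULL = auto).
#' @param hyperemia list: `peak_gain`, `dip_depth`, `recovery_tau_s` for the
#'   post-reperfusion overshoot / secondary-dip / slow-recovery envelope.
#' @param collateral list: `gain` (relative BFI rise per unit occupancy) and
#'   `flow_gain` baseline collateral velocity.
#' @param sd list: `speed_mm_min` propagation speed, `amplitude` fractional
#'   trough depth, `width_s` temporal Gaussian sigma, `delay_s` onset after
#'   complete occlusion; `amplitude = 0` disables the wave.
#' @param cortex list: `severity_max`, `severity_min`, `length_px` spatial
#'   decay of the ischemic-severity field with distance from the vessel,
#'   `window_severity` severity of the parenchyma inside the vessel window.
#' @param speckle list: `g` flow-to-N gain (`N = round(1 + g * flow)`,
#'   expected contrast `1/sqrt(N)`), `mean_counts` detector counts at unit
#'   intensity, `bit_depth` 8 or 16.
#' @param noise list: `shot_scale` multiplier on sqrt(counts) shot noise,
#'   `dark_offset` counts added to every pixel.
#' @param seed integer RNG seed.
#' @return object of class `synth_config` (a validated named list).
#' @export
synth_config <- function(frame_size = c(64L, 128L),
                         um_per_pixel = 5,
                         exposure_time_ms = 10,
                         rate_schedule = list(c(0, 10), c(400, 2)),
                         duration_s = 900,
                         baseline_duration_s = 30,
                         light = list(),
                         kinetics = list(),
                         vessel = list(),
                         hyperemia = list(),
                         collateral = list(),
                         sd = list(),
                         cortex = list(),
                         speckle = list(),
                         noise = list(),
                         seed = 1L) {
  merge_block <- function(user, defaults, name) {
    if (!is.list(user)) stop(sprintf("config block '%s' must be a list", name))
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop(sprintf("unknown keys in config block '%s': %s", name,
                   paste(unknown, collapse = ", ")))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    frame_size = as.integer(frame_size),
    um_per_pixel = um_per_pixel,
    exposure_time_ms = exposure_time_ms,
    rate_schedule = rate_schedule,
    duration_s = duration_s,
    baseline_duration_s = baseline_duration_s,
    light = merge_block(light, list(
      mode = "feedback", intensity = 1, feedback_lag_s = 0.5,
      feedback_threshold = 0.10, duration_s = 300,
      max_duration_s = 1800), "light"),
    kinetics = merge_block(kinetics, list(
      k_on = 3.7e-4, k_auto = 0.0303, k_off = 4.4e-4, dye_level = 1,
      persist_tau_s = 75, detach_frac = 0.80, detach_rate = 0.15,
      jitter_sd = 0.03), "kinetics"),
    vessel = merge_block(vessel, list(
      d0_um = 100, flow_gain = 8, dead_zone = 0.75, flux_exponent = 4,
      velocity_cap = 3, center_col = NULL), "vessel"),
    hyperemia = merge_block(hyperemia, list(
      peak_gain = 0.35, dip_depth = 0.20, recovery_tau_s = 80), "hyperemia"),
    collateral = merge_block(collateral, list(
      gain = 0.6, flow_gain = 6), "collateral"),
    sd = merge_block(sd, list(
      speed_mm_min = 3, amplitude = 0.35, width_s = 2, delay_s = 15), "sd"),
    cortex = merge_block(cortex, list(
      severity_max = 0.80, severity_min = 0.02, length_px = 18,
      window_severity = 0.6), "cortex"),
    speckle = merge_block(speckle, list(
      g = 24, mean_counts = 8000, bit_depth = 16L), "speckle"),
    noise = merge_block(noise, list(
      shot_scale = 1.0, dark_offset = 50), "noise"),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (length(cfg$frame_size) != 2L || any(cfg$frame_size < 16L))
    stop("frame_size must be two integers >= 16")
  if (cfg$um_per_pixel <= 0) stop("um_per_pixel must be positive")
  rs <- cfg$rate_schedule
  if (!length(rs)) stop("rate_schedule must not be empty")
  starts <- vapply(rs, function(x) x[[1L]], numeric(1))
  rates <- vapply(rs, function(x) x[[2L]], numeric(1))
  if (starts[1L] != 0) stop("rate_schedule must start at t = 0")
  if (any(diff(starts) <= 0)) stop("rate_schedule start times must increase")
  if (any(rates <= 0)) stop("acquisition rates must be positive")
  k <- cfg$kinetics
  if (k$k_on < 0 || k$k_off < 0 || k$k_auto < 0)
    stop("kinetic rates must be non-negative")
  if (k$detach_rate <= 0 || k$persist_tau_s <= 0)
    stop("detach_rate and persist_tau_s must be positive")
  if (cfg$duration_s <= cfg$baseline_duration_s)
    stop("duration_s must exceed baseline_duration_s")
  if (!cfg$light$mode %in% c("feedback", "fixed", "off"))
    stop("light$mode must be 'feedback', 'fixed' or 'off'")
  if (cfg$light$intensity < 0) stop("light intensity must be >= 0")
  v <- cfg$vessel
  if (v$d0_um <= 0 || v$dead_zone <= 0 || v$dead_zone > 1)
    stop("vessel d0_um must be positive and dead_zone in (0, 1]")
  if (!cfg$speckle$bit_depth %in% c(8L, 16L))
    stop("speckle bit_depth must be 8 or 16")
  invisible(cfg)
}

#' Frame timestamps implied by an acquisition-rate schedule
#'
#' @param rate_schedule list of `c(start_s, hz)` pairs.
#' @param duration_s total duration.
#' @return numeric vector of timestamps (seconds, strictly increasing,
#'   starting at 0).
#' @export
schedule_timestamps <- function(rate_schedule, duration_s) {
  starts <- vapply(rate_schedule, function(x) x[[1L]], numeric(1))
  rates <- vapply(rate_schedule, function(x) x[[2L]], numeric(1))
  ends <- c(starts[-1L], duration_s)
  ts <- numeric(0)
  t_next <- 0
  for (i in seq_along(starts)) {
    if (t_next >= ends[i]) next
    seg <- seq(t_next, ends[i] - 1e-9, by = 1 / rates[i])
    ts <- c(ts, seg)
    t_next <- seg[length(seg)] + 1 / rates[i]
  }
  ts
}
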