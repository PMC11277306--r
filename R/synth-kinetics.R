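# Thrombosis kinetics and the open-loop flow-movie generator.
#
# Thrombus occupancy theta in [0,1] follows
#   light on :  dtheta/dt = (k_on*I*dye + k_auto*theta) * (1-theta) - k_off*theta
#   light off:  dtheta/dt = k_auto*exp(-(t-t_off)/persist_tau) * theta*(1-theta)
#                           - k_off*theta
#   detached :  dtheta/dt = -(detach_rate + k_off) * theta
# The autocatalytic term models platelet recruitment (delayed narrowing onset
# followed by rapid occlusion); the persistence term lets the clot keep
# growing briefly after illumination stops; detachment (triggered when the
# decaying occupancy falls below `detach_frac`) models the abrupt thrombus
# separation that starts reperfusion.

KINETICS_DT <- 0.1  # fine integration step, seconds (RK4)

kinetics_init <- function(cfg, rates = NULL) {
  k <- cfg$kinetics
  if (is.null(rates)) rates <- list(k_on = k$k_on, k_auto = k$k_auto,
                                    k_off = k$k_off)
  list(theta = 0, t = 0, mode = "idle", theta_peak = 0,
       t_on = NA_real_, t_off = NA_real_, t_detach = NA_real_,
       rates = rates)
}

kinetics_deriv <- function(theta, t, st, cfg) {
  k <- cfg$kinetics; r <- st$rates
  drive <- switch(st$mode,
    idle = 0,
    on = (r$k_on * cfg$light$intensity * k$dye_level + r$k_auto * theta) *
      (1 - theta),
    post = r$k_auto * exp(-(t - st$t_off) / k$persist_tau_s) *
      theta * (1 - theta),
    detached = -k$detach_rate * theta)
  drive - r$k_off * theta
}

# Advance the kinetic state to time t1 with the illumination command given by
# light_on(t, theta) (a function, evaluated at sub-step resolution), so
# feedback shutoff rules see the current occupancy.
kinetics_advance <- function(st, t1, light_on, cfg) {
  k <- cfg$kinetics
  while (st$t < t1 - 1e-12) {
    dt <- min(KINETICS_DT, t1 - st$t)
    on <- isTRUE(light_on(st$t, st$theta))
    if (on && st$mode == "idle") { st$mode <- "on"; st$t_on <- st$t }
    if (!on && st$mode == "on") { st$mode <- "post"; st$t_off <- st$t }
    if (st$mode == "post") {
      st$theta_peak <- max(st$theta_peak, st$theta)
      # the clot detaches once its slow dissolution has eroded it below
      # detach_frac (only after the post-illumination growth has peaked)
      if (st$theta <= k$detach_frac && st$theta < st$theta_peak - 1e-9) {
        st$mode <- "detached"; st$t_detach <- st$t
      }
    }
    f <- function(th, tt) kinetics_deriv(th, tt, st, cfg)
    k1 <- f(st$theta, st$t)
    k2 <- f(st$theta + dt / 2 * k1, st$t + dt / 2)
    k3 <- f(st$theta + dt / 2 * k2, st$t + dt / 2)
    k4 <- f(st$theta + dt * k3, st$t + dt)
    st$theta <- min(1, max(0, st$theta + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)))
    st$t <- st$t + dt
  }
  st
}

#' Relative volumetric flux through the vessel as a function of occupancy
#'
#' Flux is conserved at baseline while the lumen narrows above the dead zone
#' (velocity rises through the stenosis), then collapses with a power law.
#'
#' @param theta thrombus occupancy in `[0, 1]` (vectorized).
#' @param vessel the `vessel` block of a [synth_config()].
#' @return relative flux (1 = baseline).
#' @export
vessel_flux <- function(theta, vessel) {
  dn <- pmax(0, 1 - theta)
  ifelse(dn >= vessel$dead_zone, 1,
         (dn / vessel$dead_zone)^vessel$flux_exponent)
}

#' Relative flow velocity in the vessel as a function of lumen fraction
#'
#' Above the dead zone the flux is conserved so the velocity rises as
#' `1/x^2` with the shrinking lumen fraction `x`; below it the pressure
#' gradient can no longer drive the baseline flux and the velocity collapses
#' together with the lumen (`(x/dz)^(q-2)/dz^2` with `q = flux_exponent`, so
#' `velocity * x^2` follows the flux law of [vessel_flux()] exactly). Evaluated on the
#' rendered (pixel-quantized) lumen fraction so the rendered blood flow is
#' smooth in the lumen width.
#'
#' @param lumen_frac lumen width relative to baseline, in `[0, 1]`.
#' @param vessel the `vessel` block of a [synth_config()].
#' @return relative centre-line velocity (1 = baseline).
#' @export
vessel_velocity <- function(lumen_frac, vessel) {
  x <- pmax(1e-9, lumen_frac)
  dz <- vessel$dead_zone
  v <- ifelse(x >= dz, 1 / x^2,
              (x / dz)^(vessel$flux_exponent - 2) / dz^2)
  v[lumen_frac <= 0] <- 0
  pmin(v, vessel$velocity_cap)
}

# Post-reperfusion envelope: transient overshoot, secondary dip, slow recovery.
hyperemia_env <- function(tau, hyp) {
  if (length(tau) == 0) return(numeric(0))
  u1 <- pmax(0, tau) / hyp$recovery_tau_s
  u2 <- pmax(0, tau) / (4 * hyp$recovery_tau_s)
  out <- 1 + hyp$peak_gain * u1 * exp(1 - u1) -
    hyp$dip_depth * u2 * exp(1 - u2)
  out[tau < 0] <- 1
  pmax(out, 0)
}

# Deterministic per-run jitter on kinetic rates (lognormal, seeded by caller).
jitter_rates <- function(cfg) {
  k <- cfg$kinetics
  if (k$jitter_sd <= 0)
    return(list(k_on = k$k_on, k_auto = k$k_auto, k_off = k$k_off))
  j <- exp(stats::rnorm(3, 0, k$jitter_sd))
  list(k_on = k$k_on * j[1], k_auto = k$k_auto * j[2], k_off = k$k_off * j[3])
}

#' Scene geometry implied by a simulator configuration
#'
#' Lays out the vessel, the collateral vessel, the cortex with its MCA/ACA
#' territories, the ischemic-severity field, the five vessel section lines
#' and the four cortical spreading-depression ROIs.
#'
#' @param cfg a [synth_config()].
#' @return list with masks (logical matrices), the severity field, vessel
#'   centre/footprint helpers, ROI definitions (0-based JSON convention) and
#'   SD ROI boxes.
#' @export
synth_geometry <- function(cfg) {
  nr <- cfg$frame_size[1L]; nc <- cfg$frame_size[2L]
  upp <- cfg$um_per_pixel
  d0_px <- cfg$vessel$d0_um / upp
  cx <- cfg$vessel$center_col %||% max(8L, round(nc * 0.21))

  # vessel axis through the centre of column cx: lumen widths are odd, so
  # the rendered width steps in 1-column-per-side (2 px) decrements
  footprint_cols <- function(d_px) {
    which(abs(seq_len(nc) - cx) < d_px / 2 - 1e-9)
  }
  base_cols <- footprint_cols(d0_px)
  if (!length(base_cols)) stop("vessel does not fit in the frame")

  vessel_mask <- matrix(FALSE, nr, nc); vessel_mask[, base_cols] <- TRUE
  cortex_x0 <- max(base_cols) + 10L
  if (cortex_x0 >= nc - 8L) stop("frame too narrow for a cortex region")

  # collateral strip: 12 px wide so the 7-px contrast window has a fully
  # interior core; the measurement ROI is the 6-px interior of the strip
  coll_cols <- (nc - 14L):(nc - 3L)
  coll_rows <- 6L:(nr - 5L)
  collateral_mask <- matrix(FALSE, nr, nc)
  collateral_mask[coll_rows, coll_cols] <- TRUE
  collateral_roi <- matrix(FALSE, nr, nc)
  collateral_roi[(coll_rows[3L]):(coll_rows[length(coll_rows) - 2L]),
                 (nc - 11L):(nc - 6L)] <- TRUE

  cortex_mask <- matrix(FALSE, nr, nc)
  cortex_mask[, cortex_x0:nc] <- TRUE
  cortex_mask[collateral_mask] <- FALSE

  split_col <- cortex_x0 + round((nc - cortex_x0) * 0.5)
  mca_mask <- cortex_mask & col(cortex_mask) <= split_col
  aca_mask <- cortex_mask & col(cortex_mask) > split_col

  cx_par <- cfg$cortex
  sev <- matrix(cx_par$window_severity, nr, nc)
  dcol <- pmax(0, col(sev) - cortex_x0)
  in_ctx <- col(sev) >= cortex_x0
  sev[in_ctx] <- cx_par$severity_min +
    (cx_par$severity_max - cx_par$severity_min) *
    exp(-dcol[in_ctx] / cx_par$length_px)
  sev[vessel_mask | collateral_mask] <- 0

  # five adjacent horizontal section lines across the vessel
  line_rows <- round(seq(nr * 0.25, nr * 0.75, length.out = 5))
  half <- ceiling(d0_px / 2) + 6L
  x0 <- max(0L, round(cx - half)); x1 <- min(nc - 1L, round(cx + half))
  rois <- lapply(line_rows, function(r) {
    list(line = list(x0 = x0, y0 = r - 1L, x1 = x1, y1 = r - 1L),
         window = list(x0 = x0, y0 = max(0L, r - 5L),
                       x1 = x1, y1 = min(nr - 1L, r + 3L)))
  })

  # light-spot ROI for the real-time controller: the illumination covers a
  # 250 um stretch of the vessel, so the monitoring window spans it
  spot_half <- min(25L, (nr - 12L) %/% 2L)
  light_spot_roi <- list(
    line = list(x0 = x0, y0 = round(nr / 2) - 1L,
                x1 = x1, y1 = round(nr / 2) - 1L),
    window = list(x0 = x0, y0 = round(nr / 2) - spot_half - 1L,
                  x1 = x1, y1 = round(nr / 2) + spot_half - 1L))

  # SD ROI centres stay clear of the collateral strip; on narrow frames
  # they degenerate to nearly coincident boxes (SD analysis needs a wide
  # cortex and is not meaningful there)
  sd_hi <- max(cortex_x0 + 3L, nc - 17L)
  sd_centers <- round(seq(cortex_x0 + 3L, sd_hi, length.out = 4))
  sd_rois <- lapply(sd_centers, function(cc) {
    rows <- max(1L, round(nr / 2) - 8L):min(nr, round(nr / 2) + 8L)
    cols <- (cc - 2L):(cc + 2L)
    m <- matrix(FALSE, nr, nc); m[rows, cols] <- TRUE
    m[collateral_mask | vessel_mask] <- FALSE
    m
  })

  list(nr = nr, nc = nc, cx = cx, d0_px = d0_px, w0 = length(base_cols),
       footprint_cols = footprint_cols, base_cols = base_cols,
       cortex_x0 = cortex_x0,
       masks = list(vessel = vessel_mask, collateral = collateral_mask,
                    cortex = cortex_mask, mca = mca_mask, aca = aca_mask),
       collateral_roi = collateral_roi, light_spot_roi = light_spot_roi,
       severity = sev, rois = rois,
       sd_rois = sd_rois, sd_centers = sd_centers,
       sd_spacing_um = mean(diff(sd_centers)) * upp)
}

#' Generate a synthetic relative-flow movie with ground truth
#'
#' Integrates the thrombosis kinetics under the configured illumination
#' schedule, renders per-frame relative-flow maps (vessel with a pixel-
#' quantized narrowing lumen, recruited collateral, cortical ischemia coupled
#' to vessel blood flow, a traveling spreading-depression trough), and logs
#' every event in a ground-truth object. Event times are frame-resolved:
#' they are read from the noise-free rendered traces with the same sustained
#' threshold rules the analysis uses, so they are what a noiseless
#' measurement of the rendered world would recover.
#'
#' @param cfg a [synth_config()].
#' @return list with `flow` (H x W x T array of relative flow, parenchyma
#'   baseline = 1) and `truth` (class `ground_truth`).
#' @export
generate_flow_movie <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  rates <- jitter_rates(cfg)
  geo <- synth_geometry(cfg)
  ts <- schedule_timestamps(cfg$rate_schedule, cfg$duration_s)
  nT <- length(ts)

  # --- integrate kinetics over the full run, with emulated feedback ---------
  lt <- cfg$light
  st <- kinetics_init(cfg, rates)
  light_onset <- cfg$baseline_duration_s
  fb <- new.env()
  fb$scheduled <- switch(lt$mode,
    off = light_onset,                      # never turns on
    fixed = light_onset + lt$duration_s,
    feedback = NA_real_)
  light_on <- function(t, theta) {
    if (lt$mode == "off") return(FALSE)
    if (lt$mode == "feedback" && is.na(fb$scheduled) &&
        t >= light_onset &&
        vessel_flux(theta, cfg$vessel) < lt$feedback_threshold) {
      fb$scheduled <- t + lt$feedback_lag_s
    }
    stop_at <- min(fb$scheduled, light_onset + lt$max_duration_s,
                   na.rm = TRUE)
    t >= light_onset && t < stop_at
  }
  theta_t <- numeric(nT)
  for (i in seq_len(nT)) {
    st <- kinetics_advance(st, ts[i], light_on, cfg)
    theta_t[i] <- st$theta
  }
  t_off <- st$t_off; t_detach <- st$t_detach

  # --- noise-free traces of the rendered world ------------------------------
  v <- cfg$vessel
  d_px_t <- (1 - theta_t) * geo$d0_px
  w_px_t <- vapply(d_px_t, function(d) length(geo$footprint_cols(d)),
                   integer(1))
  flux_t <- vessel_flux(theta_t, v)
  h_t <- if (is.na(t_detach)) rep(1, nT) else
    hyperemia_env(ts - t_detach, cfg$hyperemia)
  bf_eff_t <- pmin(flux_t * h_t, 2)
  w_rel_t <- w_px_t / geo$w0
  vel_t <- pmin(vessel_velocity(w_rel_t, v) * h_t, v$velocity_cap)
  bf_rend_t <- w_rel_t^2 * vel_t           # quantized-lumen flux law
  coll_rel_t <- 1 + cfg$collateral$gain * theta_t
  bf_drive_t <- pmin(pmax(bf_eff_t, 0), 1.25) # cortical driver, keeps hyperemia

  # --- kinetic (flux-based) event references, sustained 2 s -----------------
  sus <- 2
  after_light <- ts >= light_onset
  occl_on_flux <- sustained_onset(ts, after_light & bf_rend_t < 0.10, sus)
  occl_end_flux <- if (is.na(occl_on_flux)) NA_real_ else
    sustained_onset(ts, ts > occl_on_flux & bf_rend_t >= 0.10, sus)

  # --- spreading depression -------------------------------------------------
  sdp <- cfg$sd
  sd_start <- if (!is.na(occl_on_flux) && sdp$amplitude > 0)
    occl_on_flux + sdp$delay_s else NA_real_
  v_um_s <- sdp$speed_mm_min * 1000 / 60
  sd_passage <- if (is.na(sd_start)) rep(NA_real_, 4) else
    sd_start + (geo$sd_centers - geo$cortex_x0) * cfg$um_per_pixel / v_um_s

  # --- assemble flow maps ---------------------------------------------------
  nr <- geo$nr; nc <- geo$nc
  sev <- geo$severity
  par_mask <- !(geo$masks$vessel | geo$masks$collateral)
  flow <- array(0, dim = c(nr, nc, nT))
  colmat <- col(sev)
  sd_cols <- colmat >= geo$cortex_x0
  base_frame <- matrix(1, nr, nc)
  for (i in seq_len(nT)) {
    fr <- base_frame
    fr[par_mask] <- 1 - sev[par_mask] * (1 - bf_drive_t[i])
    if (!is.na(sd_start)) {
      tp <- sd_start + (colmat - geo$cortex_x0) * cfg$um_per_pixel / v_um_s
      dip <- 1 - sdp$amplitude * exp(-(ts[i] - tp)^2 / (2 * sdp$width_s^2))
      idx <- par_mask & sd_cols
      fr[idx] <- fr[idx] * dip[idx]
    }
    fr[geo$masks$collateral] <- cfg$collateral$flow_gain * coll_rel_t[i]
    # tissue revealed as the lumen narrows behaves like window parenchyma
    fr[, geo$base_cols] <- 1 - cfg$cortex$window_severity *
      (1 - bf_drive_t[i])
    lum <- geo$footprint_cols(d_px_t[i])
    if (length(lum)) fr[, lum] <- v$flow_gain * vel_t[i]
    flow[, , i] <- fr
  }

  # --- noise-free measurement-equivalent events -----------------------------
  mt <- measurement_truth(flow, ts, cfg, geo, light_onset)
  seg0 <- mt$segmentation; ons0 <- mt$onsets
  occl_on <- seg0$occlusion_onset; occl_end <- seg0$occlusion_end
  occluded_t <- !is.na(occl_on) & ts >= occl_on &
    (if (is.na(occl_end)) TRUE else ts < occl_end)

  # diameter is zero by definition throughout complete occlusion
  d_um_t <- d_px_t * cfg$um_per_pixel
  d_um_t[occluded_t] <- 0
  rel_d_t <- w_rel_t
  rel_d_t[occluded_t] <- 0

  # expected measured class fractions at maximal depression (speckle-encoded)
  g <- cfg$speckle$g
  enc <- function(f) (1 + g * f) / (1 + g)
  rel_floor <- enc(1 - sev[geo$masks$cortex])
  design_fractions <- c(
    benign = mean(rel_floor >= 0.4 & rel_floor < 0.8),
    penumbra = mean(rel_floor >= 0.2 & rel_floor < 0.4),
    infarct = mean(rel_floor < 0.2))

  truth <- structure(list(
    seed = cfg$seed,
    time_s = ts,
    traces = data.frame(
      time_s = ts, theta = theta_t, w_px = w_px_t, d_um = d_um_t,
      rel_d = rel_d_t, flux = flux_t, bf_rel = bf_rend_t,
      velocity_rel = vel_t, coll_rel = coll_rel_t, bf_drive = bf_drive_t,
      occluded = occluded_t),
    measured = mt$measured,
    events = list(
      light_onset = light_onset, light_off = t_off, detach = t_detach,
      diameter_onset = ons0$diameter_onset, flow_onset = ons0$flow_onset,
      collateral_onset = ons0$collateral_onset,
      occlusion_onset = occl_on, occlusion_end = occl_end,
      time_to_occlusion_c = seg0$time_to_occlusion_c,
      occlusion_duration_d = seg0$occlusion_duration_d,
      occlusion_onset_flux = occl_on_flux,
      occlusion_end_flux = occl_end_flux,
      status = seg0$status,
      sd_start = sd_start, sd_passage_times = sd_passage),
    region_masks = geo$masks,
    collateral_roi = geo$collateral_roi,
    sd_rois = geo$sd_rois,
    sd_spacing_um = geo$sd_spacing_um,
    rois = geo$rois,
    design_fractions = design_fractions,
    geometry = list(cx = geo$cx, w0 = geo$w0, d0_px = geo$d0_px,
                    cortex_x0 = geo$cortex_x0),
    rates = rates,
    config = cfg), class = "ground_truth")

  list(flow = flow, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  ev <- x$events
  cat("<ground_truth>", length(x$time_s), "frames,",
      sprintf("%.1f s\n", max(x$time_s)))
  cat(sprintf("  light on %.1f s, off %.1f s\n", ev$light_onset,
              ev$light_off %||% NA))
  cat(sprintf("  onsets: diameter %.1f, flow %.1f, collateral %.1f s\n",
              ev$diameter_onset, ev$flow_onset, ev$collateral_onset))
  cat(sprintf("  occlusion: %.1f - %.1f s (c = %.1f, d = %.1f)\n",
              ev$occlusion_onset, ev$occlusion_end,
              ev$time_to_occlusion_c, ev$occlusion_duration_d))
  invisible(x)
}
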