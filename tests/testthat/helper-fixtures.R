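# Shared fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a short but complete TIA episode: baseline -> stenosis -> occlusion with a
# travelling SD -> reperfusion, at 4 Hz on a 64x64 frame
small_cfg <- function(seed = 42L) {
  synth_config(seed = seed, frame_size = c(64L, 64L), um_per_pixel = 5,
               rate_schedule = list(c(0, 4)), duration_s = 330,
               baseline_duration_s = 25,
               kinetics = list(k_off = 2e-3, persist_tau_s = 30))
}

small_run <- function() {
  cached("small_run", function() run_pipeline(small_cfg()))
}

small_movie <- function() {
  cached("small_movie", function() generate_flow_movie(small_cfg()))
}

# wide-cortex episode for spreading-depression recovery: the four SD ROIs
# span ~320 um so trough-time differences are well resolved
sd_run <- function() {
  cached("sd_run", function() {
    cfg <- synth_config(seed = 77L, frame_size = c(64L, 128L),
                        um_per_pixel = 5, rate_schedule = list(c(0, 4)),
                        duration_s = 250, baseline_duration_s = 25,
                        kinetics = list(k_off = 2e-3, persist_tau_s = 30))
    mv <- generate_flow_movie(cfg)
    stack <- render_speckle(mv$flow, cfg)
    bfi <- contrast_to_bfi(compute_contrast(stack))
    ev <- mv$truth$events
    traces <- lapply(mv$truth$sd_rois, function(m) {
      df <- relative_series(bfi, c(0.5, 24), m)
      df[df$time_s >= ev$occlusion_onset & df$time_s <= ev$occlusion_end, ]
    })
    list(cfg = cfg, truth = mv$truth,
         sd = detect_sd(traces, spacing_um = mv$truth$sd_spacing_um))
  })
}

# rate-scaled configuration for closed-loop controller runs: occlusion at
# 10 Hz, recanalization within ~50 s of the stop
loop_cfg <- function(seed) {
  synth_config(seed = seed, frame_size = c(64L, 64L), um_per_pixel = 5,
               duration_s = 340, baseline_duration_s = 20,
               rate_schedule = list(c(0, 10), c(200, 2)),
               kinetics = list(k_off = 2e-3, persist_tau_s = 30))
}

# uniform-flow stack rendered so that N = round(1 + g * flow) averaging
# controls the expected contrast K = 1/sqrt(N)
render_uniform_stack <- function(n_avg, frames = 20L, side = 80L,
                                 seed = 1L) {
  cfg <- synth_config(frame_size = c(side, side),
                      noise = list(shot_scale = 0, dark_offset = 0),
                      seed = seed)
  flow <- array((n_avg - 1) / cfg$speckle$g, dim = c(side, side, frames))
  render_speckle(flow, cfg, timestamps = seq(0, by = 0.1,
                                             length.out = frames),
                 seed = seed)
}

# brute-force sigma/mu over an explicit cube, population sd
contrast_oracle <- function(frames, window = c(7L, 7L, 5L)) {
  d <- dim(frames)
  rr <- (window[1L] - 1L) %/% 2L
  rt <- (window[3L] - 1L) %/% 2L
  n_out <- d[3L] - window[3L] + 1L
  out <- array(0, dim = c(d[1L], d[2L], n_out))
  for (t in seq_len(n_out)) {
    for (i in seq_len(d[1L])) {
      for (j in seq_len(d[2L])) {
        ri <- pmin(pmax((i - rr):(i + rr), 1L), d[1L])
        cj <- pmin(pmax((j - rr):(j + rr), 1L), d[2L])
        cube <- frames[ri, cj, t:(t + window[3L] - 1L)]
        mu <- mean(cube)
        out[i, j, t] <- if (mu <= 0) 0 else
          sqrt(mean((cube - mu)^2)) / mu
      }
    }
  }
  out
}

# pixel-level exhaustive Otsu: evaluates the between-class variance of the
# actual pixel values at every candidate bin edge
otsu_oracle <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  u <- (x - lo) / (hi - lo)
  best_sb <- -Inf; best_t <- NA_real_
  for (t in seq_len(n_bins - 1L)) {
    thr <- t / n_bins
    left <- u <= thr
    w0 <- mean(left)
    if (w0 == 0 || w0 == 1) next
    sb <- w0 * (1 - w0) * (mean(u[left]) - mean(u[!left]))^2
    if (sb > best_sb + 1e-15) { best_sb <- sb; best_t <- thr }
  }
  lo + best_t * (hi - lo)
}

# step trace on a regular grid, for constructed phase fixtures
step_trace <- function(times, breaks, values) {
  idx <- findInterval(times, breaks) + 1L
  data.frame(time_s = times, value = values[idx])
}
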