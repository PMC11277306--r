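#!/usr/bin/env Rscript
# Closed-loop feedback: the controller watches streaming single-frame
# contrast at the light spot and cuts the illumination after k consecutive
# sub-threshold blood-flow frames; the thrombus then grows on briefly,
# detaches, and the vessel recanalizes.

suppressPackageStartupMessages(library(tiaflow))

runs <- lapply(1:6, function(s) {
  cfg <- synth_config(seed = s, frame_size = c(64L, 64L), um_per_pixel = 5,
                      duration_s = 340, baseline_duration_s = 20,
                      rate_schedule = list(c(0, 10), c(200, 2)),
                      kinetics = list(k_off = 2e-3, persist_tau_s = 30))
  r <- run_closed_loop(cfg)$report
  data.frame(seed = s, stop_time_s = r$stop_time, c_s = r$c_s, d_s = r$d_s,
             latency_s = r$latency_s, timeout = r$timeout,
             recanalized = !is.na(r$occlusion_end))
})
tab <- do.call(rbind, runs)
print(tab, row.names = FALSE)
write.csv(tab, "results/closed_loop.csv", row.names = FALSE)
cat(sprintf("\nmax detection latency %.2f s (k = 5 frames at 10 Hz = 0.5 s)\n",
            max(tab$latency_s)))
cat(sprintf("recanalization after stop in %d/%d runs\n",
            sum(tab$recanalized), nrow(tab)))
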