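#!/usr/bin/env Rscript
# Simulate one complete photothrombotic TIA episode under the default study
# conditions (10 ms exposure, 10 Hz dropping to 2 Hz at 400 s, feedback-
# stopped illumination) and store it as an on-disk fixture with its ground
# truth.

suppressPackageStartupMessages(library(tiaflow))

out <- "results/episode"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(seed = 1L)
movie <- generate_flow_movie(cfg)
stack <- render_speckle(movie$flow, cfg)
write_fixture(stack, movie$truth, out)

ev <- movie$truth$events
events <- data.frame(event = names(Filter(is.numeric, ev)),
                     time_s = unlist(Filter(is.numeric, ev)))
write.csv(events, file.path(out, "events.csv"), row.names = FALSE)

cat(sprintf("simulated %d frames over %.0f s\n", length(stack$timestamps),
            max(stack$timestamps)))
cat(sprintf("light on at %.0f s, off at %.1f s (feedback)\n",
            ev$light_onset, ev$light_off))
cat(sprintf("occlusion %.1f-%.1f s: c = %.1f s, d = %.1f s\n",
            ev$occlusion_onset, ev$occlusion_end, ev$time_to_occlusion_c,
            ev$occlusion_duration_d))
cat("fixture written to", out, "\n")
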