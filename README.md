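# tiaflow

Quantitative analysis of laser speckle contrast imaging (LSCI) for
photothrombotic transient-ischemic-attack (TIA) experiments on the distal
middle cerebral artery (dMCA), with a seeded synthetic simulator so the
entire chain is testable without animal recordings.

In this experimental paradigm a spatial light modulator (SLM) shapes the
excitation laser into a small spot (50 × 250 µm, about half the vessel
diameter) on the dMCA of a photosensitizer-injected mouse. A thrombus grows
until the vessel occludes; real-time LSCI feedback stops the illumination
at complete occlusion, and the unstable clot detaches spontaneously
minutes later. The package implements, as reusable functions:

* **Speckle → flow**: spatiotemporal speckle contrast `K = σ/µ` over a
  7 × 7 × 5 voxel cube and the blood flow index `BFI = 1/K²`
  (`compute_contrast()`, `contrast_to_bfi()`).
* **Vessel metrics**: per-frame Otsu segmentation, diameter `D` as the
  longest vessel run on a section line, and blood flow
  `BF = πD²/4 · BFI` over five adjacent ROIs (`otsu_threshold()`,
  `measure_diameter()`, `blood_flow()`, `vessel_trace()`).
* **TIA phases**: baseline / stenosis / complete occlusion (relative
  BF < 10%) / reperfusion, onset times of diameter narrowing, flow
  reduction and collateral recruitment, time-to-occlusion `c`, occlusion
  duration `d`, and two-episode comparison (`segment_phases()`,
  `onset_times()`, `compare_episodes()`).
* **Cortex**: pixelwise ischemia severity (normal ≥ 80%, benign 40–80%,
  penumbra 20–40%, infarct < 20% of baseline BFI), area-fraction time
  courses, spreading-depression (SD) detection with propagation speed, and
  pixelwise Pearson correlation maps against the vessel's diameter or
  blood-flow trace (`classify_ischemia()`, `area_fraction_series()`,
  `detect_sd()`, `correlation_map()`).
* **Feedback controller**: streaming single-frame contrast at the light
  spot with a debounced stop rule, closed against the simulator
  (`controller_step()`, `run_closed_loop()`).
* **Holography**: weighted Gerchberg–Saxton SLM phase maps for arbitrary
  spot patterns with efficiency/uniformity metrics and a zero-order block
  (`make_target()`, `gsw_phase()`, `reconstruct()`).
* **Simulator**: seeded synthetic speckle recordings with full ground
  truth — autocatalytic thrombosis kinetics, flux-conserving stenosis
  hemodynamics, collateral recruitment, a travelling SD trough, and
  Gamma-sampled speckle with the analytic contrast law `K = 1/√N`
  (`synth_config()`, `generate_flow_movie()`, `render_speckle()`,
  `write_fixture()`).

See `vignettes/tiaflow-methods.Rmd` for the models, parameter meanings and
numerical choices.

## Worked example

Simulate one complete episode under the default study conditions (10 ms
exposure, 10 Hz acquisition dropping to 2 Hz at 400 s, feedback-stopped
illumination) and analyse it end to end:

```r
library(tiaflow)
run <- run_pipeline(synth_config(seed = 1))
print(run)
```

```
<tia_run> seed 1 - 5000 frames
  onsets (s): diameter 106.9, flow 148.8, collateral 116.7
  c = 160.0 s, d = 451.5 s (complete)
  max fractions: benign 0.89 penumbra 0.18 infarct 0.00
  mean r: BF 0.57 vs D 0.55; strong areas 0.55 vs 0.54
```

Reading the output: illumination starts at 30 s, so the vessel diameter
begins to narrow ~77 s after light onset and the collateral vessel is
recruited shortly after, while the vessel's blood flow holds its baseline
for another ~42 s — narrowing above the dead zone is flux-conserving,
which is exactly why blood flow is the more specific occlusion indicator.
Complete occlusion (relative BF < 10%) is reached `c` = 160 s after light
onset; the feedback stops the light there, the clot keeps growing briefly,
then lyses and detaches, and the vessel recanalizes after `d` = 451 s of
occlusion. During occlusion about a third of the cortex is benignly
ischemic (the 0.89 maximum is the moment the spreading-depression trough
sweeps the field), one SD wave crosses the cortical ROIs, and the cortical
BFI correlates slightly more strongly with the vessel's blood flow than
with its diameter.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → blood flow → cortex → closed loop → holography),
writing tables under `results/`.

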