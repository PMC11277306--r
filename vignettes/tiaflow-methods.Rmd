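---
title: "Quantifying a photothrombotic transient ischemic attack from laser speckle imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a photothrombotic transient ischemic attack from laser speckle imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment this package quantifies

In a photothrombotic transient-ischemic-attack (TIA) model, a
photosensitizer circulates in the blood while a shaped light spot —
computed on a spatial light modulator (SLM) and roughly half as wide as the
vessel — illuminates the distal middle cerebral artery (dMCA). Reactive
oxygen species injure the endothelium, platelets aggregate, and a thrombus
grows until the vessel occludes completely. Laser speckle contrast imaging
(LSCI) watches the vessel in real time; once blood flow falls below 10% of
baseline the illumination is switched off, and the unstable clot later
detaches spontaneously, reperfusing the vessel within minutes. `tiaflow`
implements the complete quantitative chain of such an experiment — speckle
contrast to blood-flow index (BFI), vessel diameter and blood flow, TIA
phase segmentation, cortical ischemia classification, spreading-depression
(SD) detection, pixelwise correlation maps, the real-time feedback
controller, and the Gerchberg–Saxton hologram design — together with a
seeded synthetic simulator, so that every stage is testable without any
animal recording.

## Speckle contrast and the blood flow index

Moving scatterers blur the speckle pattern, so local contrast
$K = \sigma/\mu$ falls as flow rises. `compute_contrast()` evaluates $K$
over a spatiotemporal cube of $7 \times 7 \times 5$ voxels (rows × columns
× frames) with the population (divide-by-$n$) standard deviation. Spatial
borders are handled by edge replication; only temporally complete positions
are emitted, so a $T$-frame stack yields $T-4$ contrast maps. Values are
centred on the stack mean before the summed-area-table accumulation, which
keeps the fast path within ~1e-15 of a direct loop. The BFI uses the
standard LSCI estimator $\mathrm{BFI} = 1/K^2$ (the $1/K$ variant is
available via `mapping = "inv_k"`); contrast below `k_floor = 1e-3` is
capped at `bfi_cap = 1e4` so downstream statistics stay finite. Both the
exponent and the sample/population convention are deliberate choices the
source experiment leaves unstated; they are exposed as arguments.

## Vessel diameter and blood flow

The vessel is segmented per frame by Otsu's threshold (256-bin histogram on
min–max-scaled values, exact per-bin value sums, ties resolved toward the
lowest bin) on a crop around each of five adjacent regions of interest
(ROIs); the diameter is the longest contiguous vessel run along a
user-defined section line, and blood flow follows
$\mathrm{BF} = \tfrac{\pi D^2}{4}\,\mathrm{BFI}$.

Three numerical choices matter here:

* **Binarization domain.** A windowed contrast cube that straddles the
  vessel edge mixes vessel and parenchyma *variances* linearly in the
  vessel fill fraction, because all pixels share the same mean intensity.
  Otsu is therefore applied to $K^2 = 1/\mathrm{BFI}$, where the
  between-class threshold lands at ~50% fill and the binarized width equals
  the true lumen to within a pixel. Thresholding raw BFI instead
  underestimates a 20-pixel vessel by roughly 30%, because $1/K^2$ mixes
  hyperbolically.
* **Interior erosion.** The line-mean BFI erodes the vessel run by the
  contrast-window radius (3 px) before averaging, since edge pixels carry
  partial-volume contrast and would dilute the vessel velocity estimate.
* **No-vessel guard.** When the vessel class is not at least 2.2× brighter
  or darker than the rest of the crop, the crop has no segmentable vessel
  (the situation during deep occlusion, when the residual lumen's
  flow approaches that of the ischemic parenchyma) and the diameter is
  reported as zero rather than as an arbitrary run of noise.

Following the experimental convention, the diameter is also forced to zero
on frames whose relative blood flow is below the 10% occlusion threshold.

## Phase segmentation and onset times

Traces are baseline-normalized and lightly smoothed (5-sample moving
median). The episode splits into *baseline*, *stenosis* (first sustained
decrease of flow or diameter), *complete occlusion* (relative BF < 0.10)
and *reperfusion*, with `c` = light onset → occlusion and `d` = occlusion
duration. An onset is the first time a deviation beyond
`onset_eps = 0.05` is sustained for `sustain_s = 2` s. "Sustained" demands
at least 90% of the samples in the 2-s window rather than strict
consecutiveness: on noisy traces a strictly-consecutive rule only fires
after the trace clears the threshold by several noise standard deviations,
which biases every onset late by seconds; the 90% rule keeps the detection
centred on the true crossing while still rejecting single-frame dropouts.
Non-uniform timestamps (the 10 Hz → 2 Hz or 1 Hz acquisition-rate change)
are honored throughout by working in seconds, not samples. At 1 Hz the
validation analyses widen the onset median to 9 samples: the default
5-sample median then spans only 5 s, and the slow collateral ramp crosses
its threshold within the noise unless smoothed over a comparable window.

## Cortical ischemia, spreading depression, correlation maps

Relative-BFI maps are classified per pixel: *normal* ≥ 0.8 of baseline,
*benign* in [0.4, 0.8), *penumbra* in [0.2, 0.4), *infarct* < 0.2. The
published class bounds overlap at 40%; the intervals here are half-open
with each class owning its printed lower bound, and the thresholds are
arguments. Area fractions are taken over an explicit cortex mask.

SD detection receives spatially ordered ROI traces, divides each by a 30-s
running median (the ischemic background drifts during occlusion, and a
static normalization floods the depth criterion with false troughs), then
finds transient troughs deeper than 15% that recover within 60 s. Trough
times are refined by a squared-deficit centroid over ±5 s — unbiased for a
symmetric trough and far more stable than a local parabola. An SD event is
a chain of troughs in ≥ 3 consecutive ROIs with strictly increasing times;
the propagation speed comes from a linear fit of trough time against ROI
position.

Correlation maps are plain Pearson coefficients between a reference trace
(relative diameter or blood flow of the vessel) and every pixel's
relative-BFI course; zero-variance pixels are flagged undefined and
excluded from the strongly-correlated area fraction (r > 0.5).

## The synthetic episode generator

The simulator is first-class, tested code: it defines the world against
which every estimator is validated.

**Thrombosis kinetics.** Occupancy $\theta \in [0,1]$ of the lumen follows
$\dot\theta = (k_{on} I\,\mathrm{dye} + k_{auto}\theta)(1-\theta) -
k_{off}\theta$ under illumination. The autocatalytic term models platelet
recruitment: narrowing begins tens of seconds after light onset and then
accelerates, reproducing the observed ordering in which the diameter starts
to narrow (and the collateral BFI starts to rise) half a minute before the
vessel's blood flow leaves baseline. After the light stops, recruitment
decays with `persist_tau_s` (the coagulation cascade outlives the light);
once the slowly lysing clot erodes below `detach_frac` of the lumen it
detaches (`detach_rate`), reproducing the abrupt reperfusion, which is then
shaped by a hyperemic envelope (overshoot, secondary dip, slow recovery).
Defaults are calibrated so that, under the default illumination feedback,
narrowing begins ~75 s and the flow decrease ~110 s after light onset, and
the occlusion lasts ~420 s — the temporal regime of the modeled experiment.
Rates receive a 3% lognormal across-run jitter.

**Hemodynamics.** Above a dead zone (`dead_zone = 0.75` of baseline
diameter) flux is conserved: velocity rises as $1/x^2$ while the lumen
fraction $x$ shrinks, so blood flow stays at baseline while the vessel
narrows — this is what delays the flow onset relative to the diameter
onset. Below the dead zone the pressure gradient can no longer drive the
baseline flux and flux follows $(x/\mathrm{dz})^{q}$ with $q = 4$; velocity
collapses accordingly. The lumen is rendered with odd pixel widths (vessel
axis through a pixel centre), which makes the quantized blood-flow levels
straddle the 10% occlusion threshold decisively (≈ 0.19 above, ≈ 0.076
below) instead of dwelling at it; threshold crossings are then sharp events
that both the truth and any estimator date to the same frame.

**Scene.** A 64 × 128 px field at 5 µm/px: a 100-µm vertical vessel, an
8-px collateral strip whose BFI rises with $\theta$ from the moment
narrowing begins, and a cortex whose ischemic severity decays exponentially
with distance from the vessel (`severity_max = 0.8`, length 18 px). The
cortical drive follows vessel blood flow, capped at 1.25 so post-reperfusion
hyperemia reaches the cortex. During occlusion one SD trough travels across
the cortex at 3 mm/min (a literature-typical speed; the modeled experiment
states none), 35% deep and 2 s wide.

**Speckle rendering.** Contrast is encoded by averaging
$N = \mathrm{round}(1 + g\,\mathrm{flow})$ independent fully developed
speckle realizations per pixel ($g = 24$, so parenchyma baseline maps to
$N = 25$), giving the analytic oracle $K = 1/\sqrt N$. The mean of $N$
unit-mean exponential intensities is Gamma$(N, N)$-distributed and is
sampled as such in a single draw. Detector counts add a dark offset and
Gaussian shot noise with sd $\propto \sqrt{\mathrm{counts}}$, then quantize
to 16 bits.

**Ground truth is a noise-free measurement.** The rendered world is
pixel-quantized, and the spec of "true" event times is subtle: the package
defines them by running the *identical* measurement chain on the expected
BFI maps implied by the encoding ($K^2 = \overline{1/N}$ over the contrast
cube). Recovery tests therefore quantify pure estimation error from speckle
noise and sampling, not definitional mismatch. The continuous flux-law
crossing times are kept alongside (`events$occlusion_onset_flux`).

What passing tests on this generator do **not** show: robustness to motion
artifacts, illumination drift, curved or branching vessels, physiological
oscillations (heartbeat, vasomotion), or real speckle statistics beyond the
fully-developed, spatially-uncorrelated ideal. The generator emulates the
temporal structure and contrast statistics the estimators rely on, nothing
more.

## The feedback controller

The real-time path mimics causality: single-frame spatial contrast
(7 × 7, temporal depth 1), blood flow measured over the full 250-µm
light-spot window (per-row vessel runs, mean width, pooled eroded
interiors — one section line is far too noisy at one frame), and a debounce
that stops the illumination after `k = 5` consecutive sub-threshold frames
or a timeout. The counter uses a Schmitt trigger: starting requires
rel-BF < 0.10, but once counting, samples up to 0.18 do not reset it.
Without hysteresis a single transition-frame spike restarts the
confirmation window and the stop can slip several frames past the
`k`-interval bound; false entries are impossible because the level just
above the crossing sits at ≈ 0.19 with ≈ 0.4% noise. Detection latency is
reported against the causal noise-free measurement: the offline estimator's
centred temporal window sees each transition ~2 frames before any real-time
detector can.

## Hologram design

A scalar Fourier-optics model: the SLM carries a unit-amplitude field whose
unitary 2-D FFT is the focal plane (Parseval holds exactly; total power is
normalized to 1). `gsw_phase()` is the weighted Gerchberg–Saxton iteration
with per-spot weights $w \leftarrow w\,\bar a/a_{spot}$, target amplitudes
imposed on the spots (zero elsewhere), focal phase retained, and only the
pupil phase kept after back-transformation. The initial phase is random
with a fixed seed; 30 iterations by default. The zero-order block is a
3-px-radius disk zeroed in the focal plane. Efficiency is the power
fraction inside the target; uniformity is $1 - (I_{max}-I_{min}) /
(I_{max}+I_{min})$ over per-spot mean intensities.

## Problem sizes and reproducibility

The default episode is 900 s at 10 Hz → 2 Hz on a 64 × 128 field
(5000 frames); parameter-recovery studies use 50 episodes at 1 Hz on
64 × 48 fields with occlusion durations drawn from [200, 800] s, and
closed-loop studies use 400-s episodes with occlusion kinetics scaled
(`k_off = 2e-3`, `persist_tau_s = 30`) so recanalization completes within
the run. These sizes were chosen so a full validation executes comfortably
on a laptop while every phase of the episode remains represented. All
randomness is seeded: identical seeds give bit-identical stacks and
summaries; different seeds change the noise but not the event ordering.

## Known limitations

* Diameters are pixel-quantized (no sub-pixel estimation, by design); the
  binarized width tracks the rendered lumen to ~1 px but absolute accuracy
  inherits the contrast-window blur.
* The severity field, collateral gain and SD parameters are scientific
  caricatures: area fractions and correlation magnitudes are internally
  consistent but are not expected to reproduce in vivo cohort values.
* The controller assumes the camera and SLM respond within a frame;
  hardware latencies are out of scope.
* `compare_episodes()` compares two already-segmented episodes; it does not
  model between-episode biology (e.g., why a second thrombosis is faster).
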