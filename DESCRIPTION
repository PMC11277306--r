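Package: tiaflow
Title: Laser Speckle Analysis and Simulation for Photothrombotic Transient
    Ischemia Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of laser speckle contrast imaging (LSCI)
    recordings from photothrombotic transient-ischemic-attack (TIA)
    experiments targeting the distal middle cerebral artery, together with a
    seeded synthetic speckle simulator so every stage is testable without
    in vivo data. Provides spatiotemporal (7x7x5) speckle contrast and
    blood-flow-index estimation, Otsu-based vessel segmentation with
    diameter and blood-flow extraction, TIA phase segmentation (baseline,
    stenosis, complete occlusion, reperfusion) with onset-time and
    occlusion metrics, cortical ischemia severity classification and
    spreading-depression detection, pixelwise Pearson correlation maps,
    an emulated real-time occlusion-feedback illumination controller, and
    weighted Gerchberg-Saxton hologram design for spatial-light-modulator
    spot targeting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
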