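Package: veinpwv
Title: Pulse Wave Velocity Estimation in Retinal Veins from
    Photoplethysmographic Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for estimating the vessel pulse wave
    velocity (PWV) of a retinal vein segment inside the optic disc from
    photoplethysmographic (PPG) fundus video. Provides frame quality
    control and multi-stage registration, Beer-Lambert negative-log
    intensity transformation, per-pixel harmonic regression with
    first-order autoregressive errors fitted by restricted maximum
    likelihood, first-harmonic phase profiling along the vessel
    centreline, loess-guided analysis-segment selection, and PWV
    computation from the distance-phase slope. A synthetic PPG video
    simulator with known ground-truth wave speed makes every pipeline
    stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
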