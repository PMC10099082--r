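Package: ringusct
Title: Speed-of-Sound Adaptive Transmission-Reflection Ultrasound Computed
    Tomography for Ring Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for ring-array ultrasound computed tomography (USCT):
    synthetic full-view channel-data generation with a bent-ray forward model,
    first-arrival time-of-flight picking with geometric gating and AIC
    changepoint detection, speed-of-sound reconstruction by the simultaneous
    algebraic reconstruction technique (SART) with Siddon straight-ray
    weights, first-arrival travel-time maps through heterogeneous media via a
    multi-stencils fast-marching Eikonal solver, full-angle spatial
    compounding delay-and-sum (DAS) beamforming with either constant-speed or
    speed-adaptive delays, and quantitative image metrics (contrast-to-noise
    ratio, apparent size, localization error).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    EBImage,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
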