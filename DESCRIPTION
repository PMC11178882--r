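Package: scanvolt
Title: Analysis and Simulation Tools for Scanless Two-Photon Voltage Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for camera-based scanless two-photon voltage imaging
    of genetically encoded voltage indicators. Generates seeded synthetic
    fluorescence movies with Poisson shot noise, photobleaching and the
    recording protocols used to characterise soma-targeted negative-going
    indicators; extracts single-cell traces with regression-based pixel
    weighting and bleach detrending; detects action potentials by template
    matching and scores them against ground truth with precision, recall and
    F1; averages sub-threshold trials; runs centre-of-mass motion quality
    control; and simulates light-induced tissue heating with a Green's
    function heat-diffusion model, method-of-images surface boundary and a
    phase-screen beam-propagation scattering engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    zoo,
    tiff,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
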