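Package: transsacc
Title: Transsaccadic Perceptual-Grouping Stimuli and Eye-Movement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying perceptual grouping of object contours across
    saccadic eye movements. Generates radial-frequency-pattern stimulus displays
    (latent contour pairs, jittered element placement, proximity-cue elimination,
    target placement with stratified inside/outside allocation), renders
    Gaussian-blob preview and Gabor test displays, simulates trial-level
    behavioral and eye-movement data with configurable condition structure, and
    implements the analysis pipeline: trial censoring, discrete-time
    survival/hazard functions, landing-accuracy-adjusted reaction-time contrasts,
    analysis of variance of variance for landing spread, logistic accuracy
    models, landing iso-frequency maps, and coarse-shape (minimum bounding
    rectangle) analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
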