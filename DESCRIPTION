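Package: dpstr
Title: Simulation and Quantification of Dynamic Protein Synthesis
    Translocation Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell analysis of nuclear-translocation
    expression reporters (dPSTR) in time-lapse microscopy. Provides a
    stochastic simulator of osmostress signalling, promoter switching and
    reporter kinetics; a synthetic multichannel movie renderer with ground
    truth masks; nucleus/cytoplasm segmentation, tracking and quality
    control; per-cell expression and signalling metrics (nuclear
    enrichment, basal correction, expression output and timing, Hog1
    signalling output, transcription-site statistics, half-life
    estimation); and time-resolved intrinsic/extrinsic expression-noise
    decomposition for dual-reporter cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
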