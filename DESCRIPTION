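Package: painface
Title: Phasic Pain Intensity Recognition from Facial Expression Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for recognising experimentally induced phasic pain
    intensity (baseline plus heat and electrical stimuli at three calibrated
    intensities, seven classes in all) from facial video. Implements a
    spatio-temporal three-frame image encoding, the 48-statistic facial
    activity descriptor computed from OpenFace action-unit intensity time
    series, random-forest and two-branch convolutional-network classifiers
    with optional multi-task heads, a score-threshold sample-duplication
    weighting scheme for noisy no-response samples, subject-disjoint
    stratified cross-validation, and a harness for comparing machine
    predictions with human-observer label files. Ships a synthetic-data
    module that emulates the statistical structure of stimulus-locked facial
    responses so the full stack is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
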