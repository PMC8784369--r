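Package: surgnav
Title: Fiducial Registration, Error Modelling and Targeting Cues for
    Image-Guided Surgical Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline toolkit for the computational core of a
    microscope-integrated surgical navigation system: automated
    paired-point rigid registration of tracked sensor positions to
    fiducial centroids detected in CT-like volumes, statistical models
    of fiducial localization, fiducial registration and target
    registration error (FLE/FRE/TRE) with chi-square confidence
    ellipses and a Monte-Carlo oracle, pivot calibration of tracked
    instruments, instrument-frame lateral/depth targeting-cue geometry
    with dwell-based target capture, and postoperative placement-error
    assessment.  A synthetic-session generator emulates a
    nasopharyngeal fiducial cluster with a distant brainstem target so
    every component is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    RNifti,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
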