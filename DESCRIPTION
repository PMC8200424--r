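Package: doseqa
Title: Intrinsic Detector Sensitivity Analysis for VMAT Delivery-Error QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully synthetic re-implementation of the measurement-to-measurement
    ("intrinsic detector sensitivity") approach to patient-specific VMAT quality
    assurance. Generates lung-SBRT-like two-arc VMAT plans, injects controlled
    collimator-angle, MLC field-size and MLC bank-shift delivery errors, renders
    planar dose surrogates, virtually measures them with a sparse cylindrical
    diode-array model and a dense flat-panel (EPID) model, and quantifies error
    detectability with global gamma-index analysis (gamma pass rate and gamma
    mean value) across dose-difference/distance-to-agreement criteria, detector
    resolutions and resampling/interpolation choices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
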