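Package: gaitbouts
Title: Threshold-Based Walking-Bout Detection from Lower-Back
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects walking bouts in triaxial lower-back accelerometer
    recordings with a computationally cheap, orientation-independent
    threshold pipeline: zero-phase Butterworth detrending, the 3D
    acceleration norm, Gaussian activity-likelihood smoothing, gap
    filtering, rejection of high-intensity transients such as sit-stand
    transitions, and a minimum bout duration.  Includes a personalized
    calibration mode that derives the activity threshold from the median
    of a 24-h free-living trace, per-sample binary-classifier evaluation
    against ground-truth labels, a labelled synthetic-signal simulator
    for end-to-end testing, and delimited-text readers and writers with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
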