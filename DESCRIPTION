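Package: dfncstates
Title: Dynamic Functional Network Connectivity States from Component Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional network connectivity (DFNC)
    analysis for ICA-derived component time courses: time-course
    post-processing (detrending, despiking, low-pass filtering, nuisance
    regression, motion QC), tapered sliding-window connectivity with
    graphical-lasso regularized precision matrices and Fisher z-transform,
    k-means state clustering under the city-block metric with gap-statistic
    and silhouette cluster-number validity, per-subject state temporal
    properties (fractional windows, mean dwell time, transition counts), and
    group statistics with false-discovery-rate control over connectivity
    pairs. Includes a hidden-Markov multivariate-Gaussian cohort simulator
    with known ground truth so the whole pipeline can be validated without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    yaml
Config/testthat/edition: 3
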