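Package: ctdcsnet
Title: Functional Brain Network Analysis and Outcome Prediction for
    Cathodal tDCS in Focal Epilepsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse resting-state fMRI functional networks around
    cathodal transcranial direct current stimulation (ctDCS) in focal
    epilepsy. Builds Fisher-z Pearson connectivity matrices from parcellated
    region-of-interest time series, thresholds them to fixed-density weighted
    graphs across a density sweep, computes weighted graph-theoretical
    measures (degree, Onnela clustering, characteristic path length, global
    and local efficiency, small-worldness against degree-preserving rewired
    nulls), compares pre- versus post-stimulation measures with
    normality-gated paired tests under false-discovery-rate correction, and
    predicts treatment response from measure change rates with maximal
    information coefficient feature ranking, sequential forward selection and
    nested cross-validated RBF support vector machines. A synthetic cohort
    generator with modular AR(1) BOLD-like signals and Poisson seizure
    diaries makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
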