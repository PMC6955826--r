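Package: fnconn
Title: Functional Network Connectivity of Resting-State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise large-scale functional network connectivity
    (FNC) between resting-state networks (RSNs) from multivariate time-courses.
    Connectivity is estimated with the lag-maximised (circular-shift) distance
    correlation and screened against circular-rotation surrogates; the retained
    weighted network is summarised with integration (degree, strength),
    segregation (weighted clustering coefficient) and centrality (betweenness,
    eigenvector) measures, and groups are compared with Welch t tests under
    Bonferroni correction. A synthetic-cohort generator produces coupled,
    band-limited RSN time-courses with graded connectivity degradation, spatial
    component maps for template matching, spatio-temporal component
    fingerprints with a neuronal/artifactual classifier, and rigid-body motion
    traces for frame-wise displacement quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    withr,
    yaml,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
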