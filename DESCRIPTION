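Package: complexbold
Title: Temporal and Topological Complexity of Parcellated Brain Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying the complexity of parcellated
    fMRI BOLD time-series in both the temporal and the topological
    (functional-network) domain. Implements normalised Lempel-Ziv (LZ76)
    compressibility of binarised multichannel signals, sample entropy,
    PCA compressibility, rescaled-range Hurst exponent estimation,
    Higuchi fractal dimension, and threshold-integrated graph measures
    (algebraic connectivity and adjacency-matrix compressibility) on
    Pearson functional-connectivity graphs. Includes a synthetic-cohort
    generator with known ground truth (fractional Gaussian noise by
    circulant embedding, community-coupled AR(1) region signals with a
    graded sedation-like loss of complexity), and higher-order cohort
    analysis: inter-metric correlations, an overall-complexity principal
    component, non-parametric condition comparisons and dose-response
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    pracma,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
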