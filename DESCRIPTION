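Package: longconn
Title: Longitudinal Graph-Theoretic Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for paired (baseline vs follow-up)
    resting-state functional connectome topology: Fisher-z functional
    connectivity from ROI time series, sparsity-grid binarization with exact
    edge counts, binary small-world metrics normalized against
    degree-preserving rewired null networks, AUC summarization across the
    sparsity range, group-level modularity and community detection with
    module-block edge accounting and participation coefficients, and a
    normality-gated paired statistical layer with family-scoped FDR and
    Spearman clinical correlations. Includes a synthetic paired-cohort
    generator with planted modular structure, hubs and follow-up effects so
    every stage is testable against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
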