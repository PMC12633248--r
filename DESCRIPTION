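Package: neurocrit
Title: Criticality and Excitation-Inhibition Metrics for Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Band-wise criticality and excitation-inhibition analysis of
    resting-state EEG. Generates synthetic two-group EEG cohorts with
    controllable long-range temporal correlations, bistable envelope power
    and amplitude-fluctuation coupling; decomposes recordings into 13
    log-spaced band envelopes; computes detrended fluctuation analysis (DFA)
    exponents, the functional excitation-inhibition ratio (fE/I), a
    biexponential bistability index with high/low-power ratio and separation
    indices, and Lempel-Ziv complexity; runs covariate-adjusted group
    statistics (Welch tests, Cohen's d, Benjamini-Hochberg FDR, robust IRLS
    regression, Freedman-Lane permutation) and sparse logistic classification
    with the one-standard-error rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    rlang,
    ggplot2,
    glmnet,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
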