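Package: synergizer
Title: Space-by-Time Decomposition of Muscle Activity with Task Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts spatial and temporal modules (muscle synergies) from
    single-trial electromyographic recordings by sample-based non-negative
    matrix tri-factorization (sNM3F), factoring each trial as a product of
    shared temporal modules, trial-specific activation coefficients and shared
    spatial modules. A task-discriminative extension (DsNM3F) adds a Fisher
    within-/between-task scatter penalty on the activation coefficients so the
    decomposition both reconstructs the data and separates the motor tasks.
    Provides multiplicative-update, constrained alternating least-squares and
    nonlinear-programming solvers, decoding-based evaluation metrics (VAF,
    leave-one-out LDA decoding, VDM, SVM generalization), tuning of the
    discrimination weights, model-order selection, EMG preprocessing
    (envelope extraction, time and amplitude normalization), plain-text I/O
    and a ground-truthed synthetic EMG generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
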