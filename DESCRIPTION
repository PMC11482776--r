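Package: hifit
Title: Hybrid Feature Screening and Permutation Importance Testing for
    High-Dimensional Biomarker Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage identification of outcome-associated features in
    high-dimensional biomedical data. Hybrid feature screening (HFS) ranks
    every feature by a pair of marginal utilities -- the adjusted R-squared
    (or McFadden pseudo R-squared) of a polynomial regression and a kernel
    partial correlation -- and flags candidates whose utility pair is
    anomalous under an isolation forest. The candidate set is then refined
    with a permutation-based feature importance z-test (PermFIT) over
    machine-learning models (radial-kernel support vector machines, random
    forests, gradient-boosted trees, and a bagged-and-filtered neural-network
    ensemble), orchestrated in a nested cross-validation that keeps cutoff
    tuning and importance estimation on disjoint data. Includes simulation
    generators for linear and nonlinear outcome models, evaluation metrics,
    broom-style tidiers, ggplot2 autoplot methods, and a small command-line
    interface.
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
    glmnet,
    jsonlite,
    optparse,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
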