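Package: gradstates
Title: Functional Connectivity Gradients and Dynamic Brain States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of parcellated resting-state BOLD time series along two
    complementary axes: cortical functional gradients obtained by diffusion-map
    embedding of connectivity-similarity matrices (with group-template Procrustes
    alignment, z-scoring and network dispersion summaries), and dynamic functional
    connectivity states obtained by sliding-window correlation and k-means
    clustering (with elbow/silhouette/Calinski-Harabasz model selection and
    fractional-occupancy, dwell-time and transition metrics). Includes
    covariate-adjusted group contrasts with false-discovery-rate and
    max-statistic permutation control, clinical correlation helpers,
    leave-one-out cross-validated linear support-vector classification, and a
    synthetic cohort generator that plants a connectivity hierarchy,
    Markov-switching covariance states, group effects and clinical covariates
    with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
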