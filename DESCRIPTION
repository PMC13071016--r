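Package: fedprosim
Title: Privacy-Aware Federated Learning Simulation for Medical Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates cross-silo federated learning for multi-class medical-style
    image classification on a single machine. Provides a synthetic image generator
    with class-structured lesion motifs, Dirichlet non-IID client partitioning,
    a small convolutional backbone trained with Adam (plus analytic layer
    inventories for standard large backbones), layer-skipped local training,
    sample-count-weighted FedAvg model aggregation, class-prototype aggregation,
    differential-privacy perturbation (norm clipping plus Gaussian noise),
    simulated secure aggregation by pairwise additive masking, analytic
    communication-cost accounting, privacy-leakage scoring, and NSGA-II
    multi-objective optimization over accuracy, communication and privacy
    objectives. Tabular results are returned as tibbles with broom-style tidy()
    and glance() methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    withr,
    stats,
    utils,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    jpeg
Config/testthat/edition: 3
RoxygenNote: 7.3.3
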