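Package: dante
Title: Deep Active Optimization with Neural-Surrogate-Guided Tree Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-efficient active-optimization loop for expensive black-box
    design problems. A deep one-dimensional convolutional surrogate is trained
    on a small labeled dataset, the discrete design space is explored with a
    visitation-count tree search governed by a data-driven upper confidence
    bound (DUCB), and small batches of candidates are proposed for labeling in
    a closed loop. Ships discretized high-dimensional synthetic benchmarks
    (Ackley, Rosenbrock, Rastrigin, Griewank, Schwefel, Michalewicz), a
    peptide-sequence design application over the 20-letter amino-acid alphabet
    with a synthetic binder-fitness oracle, ablation switches for every search
    mechanism, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr,
    withr
Config/testthat/edition: 3
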