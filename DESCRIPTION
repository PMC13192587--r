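Package: causaljudge
Title: Causal Judgment from Stochastic Observations with Task-Optimized
    Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a cued causal-judgment task in which binary
    observations are sampled from noisy-or parameterized directed acyclic
    graphs (DAGs), trains leaky tanh recurrent neural networks to judge
    queried cause-effect relations from those observations, and provides a
    reverse-engineering toolkit for the trained networks: an exact Bayesian
    ideal observer over enumerated DAG structures, behavioral probes
    (category-wise accuracy, transitivity bias, circular-shuffle controls,
    implicit whole-graph readout), and dynamical-systems analyses
    (fixed-point finding under tonic query input, line-attractor geometry,
    Jacobian eigenmodes, and input-effect maps).
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
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
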