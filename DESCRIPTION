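Package: trajlm
Title: Character-Level Language Models of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns probabilistic sequence models of spatially discretized
    one-dimensional order-parameter trajectories using an embedding + LSTM +
    softmax architecture, and generates statistically equivalent synthetic
    trajectories. Includes an overdamped Langevin simulator for a family of
    two-dimensional model potentials (linear three-state, triangular
    three-state, and four-state), spatial discretization into one-hot
    characters, commit-time transition counting, Boltzmann occupancy and free
    energy estimation, an embedding-layer kinetic distance, and closed-form
    Markov-chain references (entropy rates, maximum-likelihood transition
    estimates, mean first-passage commute times) used as statistical oracles.
    The recurrent network core (forward pass, backpropagation through time,
    Adam/SGD, autoregressive sampling) is implemented in C++ via
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
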