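Package: mlcycle
Title: Stochastic May-Leonard Models: Extinction, Stationarity and Cycle
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-state stochastic implementations of the May-Leonard
    three-species competition model and a related three-pool central pattern
    generator model. Provides mass-action reaction networks with exact
    Gillespie simulation, deterministic mean-field integration with
    Poincare-section cycle detection, sparse infinitesimal-generator
    construction on truncated lattices with first-passage location and
    first-passage time solvers, analytic truncated-Poisson stationary
    distributions with goodness-of-fit testing, and Gamma-based cycle-length
    statistics for stochastic heteroclinic cycling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rlang,
    igraph,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
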