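Package: loopmoments
Title: Moment-Based Parameter Inference for a Negative Autoregulatory
    Gene Feedback Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and moment-based inference tools for the stochastic
    negative autoregulatory transcriptional feedback loop with geometric
    translational bursting. Generates synthetic population snapshot data by
    exact stochastic simulation (Gillespie algorithm), computes reference
    time-dependent moments by finite state projection of the chemical master
    equation, approximates the moment likelihood with six closure schemes
    (linear noise approximation, three-moment approximation, derivative
    matching, conditional derivative matching, conditional Gaussian, and the
    linear-mapping approximation), and estimates kinetic parameters by
    maximum likelihood (adaptive differential evolution) or adaptive
    Metropolis MCMC, for identical cells and for populations with lognormal
    cell-to-cell variation in the protein production rate. Includes error
    metrics and experiment drivers quantifying estimation accuracy as a
    function of sample size, number of time points, moment order and closure
    choice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
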