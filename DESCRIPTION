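Package: sglv
Title: Resilience Analysis for Stochastic Generalized Lotka-Volterra Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the resilience of microbial communities whose
    abundance dynamics follow a stochastic generalized Lotka-Volterra (SgLV)
    model with multiplicative environmental noise. Provides positivity-preserving
    Euler-Maruyama simulation on the log scale, persistence/extinction
    classification from boundary Lyapunov exponents (analytic for two species,
    Monte-Carlo invasion rates in general), statistical linearization at the
    stationary distribution, first- and second-moment ODE systems built by
    Kronecker vectorization, and four pulse-perturbation resilience measures:
    the instantaneous return rate, the average return rate, the convergence
    rate, and the asymptotic resilience.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
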