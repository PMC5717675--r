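Package: opinionet
Title: Competing Opinion Diffusion on Networks with Committed Agents and Mass Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and closed-form analysis of a multi-opinion,
    fitness-weighted voter process on networks. Supports Barabasi-Albert
    scale-free substrates and arbitrary simple connected graphs, degree-dependent
    persuasiveness (fitness), committed (zealot) agents that never change opinion,
    and a global mass-media field adopted with a tunable probability. Provides
    the conserved degree-and-fitness-weighted opinion fraction, fixation (exit)
    probabilities, steady-state opinion shares with committed agents and media,
    the decomposition of the media opinion's final share into committed, network
    amplification and media components, critical media strength via bisection,
    and a heterogeneous mean-field layer of degree-class ODEs integrated
    numerically and solved in closed form. Results are returned as tibbles with
    broom-style tidy()/glance() methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
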