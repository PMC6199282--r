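Package: heterogame
Title: Spatial Prisoner's Dilemma with Heterogeneous Environments and
    Preference Selection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulator for the weak prisoner's dilemma on a
    periodic square lattice in which every player carries a quenched
    heterogeneity value. Fitness mixes the game payoff with the mean
    heterogeneity of the four-neighbour environment (weight u), the
    imitation target is drawn by a softmax over neighbour heterogeneity
    (preference parameter alpha), and strategies are copied under the
    Fermi rule (noise K). Provides single-run, replicate-ensemble and
    parameter-sweep drivers that reproduce cooperation-level curves,
    phase diagrams and strategy snapshots; exact one-step probability
    calculators for validating the stochastic kernel; tidy result
    tables, ggplot2 figures, text-format persistence and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
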