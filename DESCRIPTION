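Package: mscoal
Title: Divergence-Time Estimation Under the Multispecies Coalescent with
    Gene Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and Bayesian inference for multilocus sequence data
    under the multispecies coalescent (MSC), the multispecies coalescent
    with introgression (MSci), and the isolation-with-migration (IM) model.
    Simulates per-locus genealogies on species networks with episodic
    introgression events or continuous migration bands, evolves sequences
    under JC69 with a strict clock, and estimates divergence times,
    population sizes, and introgression probabilities by Markov chain Monte
    Carlo. Includes stepping-stone marginal-likelihood estimation,
    Savage-Dickey Bayes factors for nested introgression hypotheses, highest
    posterior density intervals, and bias scoring of estimates against the
    generating model, for quantifying how ignoring gene flow distorts
    divergence-time estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
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
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
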