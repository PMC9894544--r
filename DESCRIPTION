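Package: adenomsce
Title: Multistage Clonal Expansion Models of Colorectal Adenoma Growth
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic cell-based analysis of colorectal adenoma growth and
    transition to cancer from categorized screening-colonoscopy records.
    Implements multi-stage clonal expansion (MSCE) models with up to two
    pre-initiating mutation stages and age trends in mutation, division and
    net clonal growth rates; a time-inhomogeneous linear birth-death
    clone-size law with closed-form extinction and size distributions; an
    interval-censored Poisson likelihood for categorical adenoma counts and
    most-advanced-adenoma size categories; maximum-likelihood fitting with a
    three-level model-selection protocol, profile-likelihood confidence
    intervals and AIC comparison; a simple cancer-risk layer (age-dependent
    transformation rate, hazard regression to crude rates, adenoma-to-cancer
    transition probabilities, interval-cancer hazard ratios versus the
    adenoma detection rate); and a fully seeded synthetic-cohort generator
    with an exact Gillespie simulator used as the correctness oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
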