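Package: oncotreefit
Title: Oncogenetic Tree Inference for Copy Number Alteration Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers oncogenetic trees describing the order of accumulation of
    binary genetic events (typically gene-level copy number alterations)
    across a tumor cohort.  Two models are provided: a branching tree fitted
    as a maximum-weight arborescence over pairwise co-occurrence weights,
    with maximum-likelihood estimation of edge firing probabilities and
    shared false-positive/false-negative observation error rates; and a
    distance-based tree with events at the leaves and hidden internal
    events, built by neighbor joining on the additive metric implied by the
    edge-probability model and refined by maximum likelihood.  Nonparametric
    bootstrap over tumors yields topology tallies and split support with a
    configurable consensus threshold.  A synthetic cohort generator
    simulates tumors from a progression tree with observation error and
    builds deterministic fixtures matching given marginal counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
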