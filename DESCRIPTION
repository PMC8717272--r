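Package: tiptempo
Title: Tip-Based Rates and Tempo of Discrete Trait Evolution on Stochastic
    Character Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three tip-based metrics of discrete-trait evolution --
    transition rate (TR), stasis time (ST) and last transition time (LT) --
    from stochastic character maps sampled under Mk models on sets of dated
    phylogenies.  Includes the machinery needed to produce those maps
    (rate-matrix construction, pruning likelihoods, maximum-likelihood model
    fitting with SYM/ARD comparison, joint node-state sampling and
    endpoint-conditioned path sampling), trait-state classification and
    imputation for percentage diet data, an equal-area spatial sampling design
    contrasting ecoregion cores and ecotones, assemblage-level averaging with
    phylogenetic-uncertainty propagation and randomization tests, Faith's
    phylogenetic diversity, and a synthetic-data generator so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    optparse,
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
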