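Package: spinestates
Title: Binary Latent States and Analog Variability of Cortical Synapse Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical modelling of synapse-size tables from dense cortical
    connectomes. Sizes of synapses between layer 2/3 pyramidal cells are
    modelled as a two-component log-normal mixture interpreted as a binary
    latent state ('S'mall or 'L'arge) plus log-normal analog variation.
    Provides maximum-likelihood mixture fitting by expectation-maximization
    (with optional lower truncation for cleft-size measurements), weight-only
    refits across connection multiplicities, bootstrap weight errors, a
    parametric bimodality likelihood-ratio test with a boundary-corrected
    (Chernoff) null, a correlated-latent-state pair model for dual
    connections fitted as a two-state chain on symmetrized pairs with the phi
    coefficient of the joint state distribution, state-conditioned resampling
    and residual tests of conditional independence, same-axon/same-dendrite
    control pairings, a distance-split analysis, and a synthetic connectome
    generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
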