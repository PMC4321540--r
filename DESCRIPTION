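Package: leafwater
Title: Leaf Water-Relations Traits and Phylogenetic Comparative Analysis for Grasses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives leaf water-relations traits from raw ecophysiological
    measurements and carries them through a phylogenetic comparative analysis.
    Pressure-volume curves are analysed by stepwise osmotic-line fitting and a
    modified-exponential turgor curve to estimate the turgor loss point, the
    saturated osmotic potential and the bulk elastic modulus. Stomatal anatomy
    yields the stomatal pore index and the anatomical maximum stomatal
    conductance; leaf-curling time series yield curling rates and cuticular
    conductance; pressure-chamber records yield leaf hydraulic conductance.
    Species trait tables are then compared with Welch tests and two-factor
    linear mixed models (subfamily by photosynthetic type, species as a random
    effect), screened for phylogenetic signal with a maximum-likelihood
    Pagel's lambda, and ordinated with conventional and phylogenetic (GLS)
    principal component analysis. A seeded synthetic-panel generator emulates
    a 33-species, 5-replicate glasshouse study so that every stage is testable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
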