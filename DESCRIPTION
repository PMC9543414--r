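Package: biomediv
Title: Biome Specialization and Diversification Rates from Incidence
    Matrices and Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify biomic specialization and link it to
    diversification in clade-level comparative analyses. Converts
    range-biome overlap fractions into binary occupancy with inclusive
    range and patch thresholds, computes the biomic specialization index
    (BSI) and specialist categories, and tests the observed BSI
    distribution against a Monte Carlo null model that holds per-biome
    species richness fixed. Computes per-tip equal-splits evolutionary
    isolation and the DR tip-rate statistic from ultrametric phylogenies,
    and provides phylogenetic comparative tests (generalized least
    squares with maximum-likelihood Pagel's lambda, simulation-based
    phylogenetic ANOVA, adjusted-R-squared variance partitioning).
    Includes seeded generators for birth-death trees, Brownian traits
    with tunable phylogenetic signal, two-state state-dependent
    diversification and right-skewed occupancy matrices, so the whole
    pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    nlme,
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
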