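Package: beemon
Title: Biodiversity Dynamics for Season-Long Wild Bee Monitoring
Version: 0.1.0
Authors@R: person("Pollinator Monitoring", "Analytics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for multi-year, season-long wild bee monitoring
    data: specimen-table ingestion and community-matrix construction, classic
    diversity metrics (abundance, richness, inverse Simpson's, evenness),
    individual-based rarefaction and species accumulation, community
    phylogenetic structure (MPD and its richness-matched standardized effect
    size on randomly grafted species-level trees), Bray-Curtis composition
    with NMDS and perMANOVA, nonlinear month/year trend fits, per-species
    standardized abundance trends with significance classes, phenology
    (seasonality and breadth) with subsampling correction, and trait models
    (OLS and Brownian-motion PGLS). Includes a synthetic monitoring-data
    simulator with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    data.table,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
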