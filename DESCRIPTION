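Package: microcore
Title: Community Assembly, Core Microbiome and Taxon-Covariate Models for
    Amplicon Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for OTU-level amplicon surveys of soil and
    other environmental microbiomes. Covers preprocessing filters and
    compositional transforms (TSS/CLR), rarefied alpha diversity, Bray-Curtis
    and unweighted UniFrac beta diversity with principal coordinate analysis,
    permutational multivariate ANOVA with stepwise distance-based RDA variable
    selection, phylogenetic null models (beta mean nearest taxon distance and
    the beta nearest taxon index), the Sloan neutral community model with
    confidence-interval partitioning of taxa, abundance-occupancy core
    microbiome selection with a Bray-Curtis contribution stopping rule,
    generalised linear latent variable models for taxon-covariate
    associations, and sparse zero-sum log-contrast (CODA-LASSO) regression.
    Includes a synthetic community generator with known ground truth for
    calibration and recovery testing, and an end-to-end seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
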