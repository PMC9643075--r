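Package: traitrisk
Title: Trait-Based Extinction-Risk Modelling with Phylogenetic Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for modelling the IUCN red-list status of insect
    species from morphological and biogeographical traits while controlling
    for phylogenetic relatedness. Extracts body volume, color lightness and
    wing area from dorsal specimen images, computes range occupancy on an
    equal-area grid, quantifies phylogenetic signal by maximum-likelihood
    estimation of Pagel's lambda, decomposes traits into phylogenetically
    predicted (P) and species-specific (S) components under Lynch's
    phylogenetic mixed model, and fits proportional-odds (ordered logistic)
    regressions of the ordinal red-list category on each component. Includes
    simulators for ultrametric trees, traits under lambda-transformed
    Brownian motion and the phylogenetic mixed model, ordinal responses,
    and rendered synthetic specimen images with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    png,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
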