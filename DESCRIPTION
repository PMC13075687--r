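Package: cladescape
Title: Scenario-Based Analysis of Spatial Species Richness Across Clades
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for deciding which richness-generating scenario
    (stable persistence, speciation balance, historical legacy, or cradles
    of diversity) best explains the spatial richness pattern of a clade.
    Delineates non-overlapping clades from a time-calibrated phylogeny by
    spectral clustering of its graph Laplacian, derives clade-specific
    biogeographic regions (evoregions) from phylogenetic turnover, fits a
    Dispersal-Extinction-Cladogenesis (DEC) model to obtain assemblage
    (arrival-time) ages, computes DR tip speciation rates, and compares
    scenario-specific path models by AIC/BIC. Includes a gridded-world
    simulator that generates clades under each scenario with full ground
    truth so every stage can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
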