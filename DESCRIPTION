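Package: seascapr
Title: Seascape Genomics of Low-Dispersal Marine Invertebrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end seascape-genomics toolkit for reef-forming marine
    invertebrates sampled as discrete sites along a coastline. Provides SNP
    filtering and per-site diversity statistics, Weir-Cockerham FST with
    permutation significance, AMOVA, FDIST-style and Bayesian F-model outlier
    scans with consensus calling, admixture-model Bayesian clustering with
    Evanno delta-K model selection, DAPC, great-circle and least-cost ocean
    distances with Mantel tests, a Lagrangian larval-dispersal simulator with
    connectivity and dispersal-resistance matrices, tide-aware intertidal
    thermal metrics, and a covariance-controlled Bayes-factor
    genotype-environment association scan. A synthetic-data generator
    emulating the statistical structure of a honeycomb-worm RADseq panel makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    vegan,
    withr
Config/testthat/edition: 3
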