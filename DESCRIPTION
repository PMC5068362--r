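Package: commdecomp
Title: Decomposition and Variation Partitioning of Multifaceted Community Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to disentangle environmental and spatial drivers of
    taxonomic, functional, and phylogenetic community structure. Builds
    axis-weighted Gower and cophenetic species distance matrices (with
    regression-based trait imputation), decomposes abundance-weighted
    trait variation into per-site composition and dispersion components,
    constructs Moran's eigenvector map (MEM) spatial predictors from site
    coordinates, and partitions variation in each response into unique
    environmental, spatially-structured environmental, unique spatial,
    and residual fractions via full and partial redundancy analysis with
    adjusted R-squared and permutation tests. Includes a synthetic
    metacommunity generator with known assembly mechanisms for
    calibration and parameter-recovery studies.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    cluster,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
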