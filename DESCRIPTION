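Package: paridmorph
Title: Geometric Morphometrics and Phylogenetic Comparative Analysis of
    Parid Body and Beak Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying morphological
    variation in tits (Paridae) and relating it to phylogeny, altitude and
    range overlap. Implements generalized Procrustes analysis with sliding
    semilandmarks for 2-D beak outlines, traditional multivariate
    morphometrics (log transformation, one-way ANOVA, principal component
    and canonical variate analysis with Mahalanobis distances, Goodall's
    Procrustes ANOVA), phylogenetic signal tests (Blomberg's K with a
    permutation test, Pagel's lambda by maximum likelihood), phylogenetic
    generalized least squares, squared-change parsimony ancestral states
    and phylomorphospace projection, and partial Mantel tests of character
    divergence against Jaccard-type range-overlap distances. A synthetic
    study generator evolves species mean traits and beak outlines by
    Brownian motion along a phylogeny, with allometry, altitudinal clines,
    within-species noise and partially overlapping ranges, so the whole
    pipeline is testable end to end without external data.
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
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nlme,
    optparse,
    phytools,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
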