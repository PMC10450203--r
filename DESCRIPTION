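Package: rnaptrack
Title: Single-Molecule Tracking Analysis of RNA Polymerase Spatial
    Organization in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-particle tracking PALM studies of
    RNA polymerase in rod-shaped bacteria. Provides spherocylindrical cell and
    prolate-spheroid nucleoid geometry with normalized-coordinate mapping, a
    four-population Monte-Carlo simulator of RNAP localizations, a two-species
    Brownian track generator and frame renderer, sub-pixel spot localization by
    elliptical Gaussian fitting, nearest-neighbour track linking with blink-gap
    closing, apparent diffusion coefficient (D*) estimation and two-gamma
    mixture fitting of mobility distributions, normalized-cell heatmaps and
    pole-proximity statistics, DBSCAN clustering of localization point
    patterns, pair-correlation functions with a geometry-matched uniform null,
    co-localization of localizations and clusters with diffraction-limited
    foci, and a replication-dependent gene-dosage model of ribosomal RNA
    operon occupancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
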