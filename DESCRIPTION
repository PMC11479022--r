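Package: germeval
Title: Morphological Diversity and Comprehensive Evaluation of Crop Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising crop germplasm collections from
    categorical descriptor data, built around the comprehensive-evaluation
    workflow used in plant genetic resources research. Computes per-trait
    Shannon-Wiener diversity indices, sigma-level binning of quantitative
    traits, covariance-matrix principal component analysis of one-hot trait
    indicators, membership-function composite scores (F-values) for accession
    ranking, stepwise selection equations, UPGMA hierarchical grouping of
    accessions, putative-variety classification rules, and a two-stage
    excellent-accession plus conservation selection. Includes a seeded
    synthetic accession generator emulating a 288-accession cardamom
    (Elettaria cardamomum) collection so every stage is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
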