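Package: kraswnt
Title: Statistics for a KRAS-MAPK-Driven WNT Ligand Niche-Escape Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical procedures for linking an oncogenic KRAS expression
    signature to autocrine WNT ligand production across cancer cell lines and
    single-cell data. Provides a tissue-stratified quartile and Spearman
    correlation screen with binary-distance clustering of significance
    profiles, signature derivation by thresholded differential expression,
    ortholog mapping and hallmark-set intersection, pseudo-bulk aggregation of
    single-cell UMI counts with single-sample gene set enrichment (ssGSEA)
    scoring under a gene-permutation null, semi-quantitative in-situ
    hybridization dot-count classification with exact contingency testing,
    expressing-cell-fraction statistics, and from-first-principles
    implementations of the rank-based and exact tests the pipeline relies on.
    Seeded synthetic-data generators with planted effects make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
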