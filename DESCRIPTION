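Package: modscore
Title: Gene-Module Expression Scores and Chromatin-Modifier Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-sample enrichment z-scores for gene modules (targets of
    histone demethylases and methyltransferases, or genes carrying a histone
    mark) against a null of random same-size modules drawn from each sample's
    expression values; Pearson-correlation signatures between enzyme
    expression and module scores; unsupervised hierarchical clustering of
    samples under the Manhattan distance; and RT-qPCR relative quantification
    by the 2^-ddCt method with well-level quality control. Includes a
    synthetic-data generator with planted latent-factor structure so every
    stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
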