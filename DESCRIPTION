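Package: targetissue
Title: Confirmation of Drug-Target Expression in Disease-Relevant Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for triaging drug targets by their expression in
    disease-relevant healthy tissues. Scores disease-tissue associations from
    literature co-occurrence counts (Ochiai coefficient, normalized to a
    maximal association score), assigns tissues per disease, binarizes bulk
    RNA-seq FPKM and ordinal immunohistochemistry protein calls, integrates
    both evidence types into per-pair confirmation categories, characterizes
    unconfirmed targets (alternate-indication and secondary-dataset rescue,
    tissue-specificity classes), and computes the accompanying summary
    statistics. Ships a synthetic-data generator with planted ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
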