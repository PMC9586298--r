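Package: cocomet
Title: Community-Modulated Secondary Metabolism from Coculture
    Transcriptomes and Metabolomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-species coculture experiments that
    asks how community composition modulates secondary metabolism.
    Quantifies biosynthetic gene cluster (BGC) expression from per-species
    RNA-seq count matrices (counts per million, low-expression filtering,
    pseudocount-based Psi log2 fold changes, BGC-wise aggregation), fits a
    per-molecular-feature 2^3 factorial linear model of species presence
    with all interactions over LC-MS metabolome feature tables and selects
    tail features by per-term t statistics, calls features present or
    absent against a knockout-anchored intensity baseline with media-blank
    subtraction, and provides sample-level ordination and Spearman
    clustering reports.  Includes a synthetic study generator with planted
    ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
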