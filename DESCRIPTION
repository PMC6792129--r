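Package: mibrkit
Title: Consensus miRNA-Binding Regions and Interactome Analysis from
    AGO-CLIP and Chimeric-Read Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating chimera-derived miRNA-mRNA interaction
    records (CLASH/CLEAR-CLIP style) with conventional AGO-CLIP peak sets.
    Provides transcript-to-genome coordinate projection, cross-dataset
    common-interaction detection with a size-matched random-placement null,
    expression-aware classification of genes (sponge-like mRNAs) and miRNAs
    (expression-to-interaction ratio types), consensus calling of
    experimentally confirmed miRNA-binding regions (Exp-MiBRs) from merged
    per-position evidence, a VCF/point query tool against the resulting
    region table, and a fully deterministic synthetic-data generator with a
    planted-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
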