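Package: triagemux
Title: Barcode Multiplexing and TRIAGE-Based Cell Typing for Single-Cell
    Differentiation Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiplexed single-cell RNA-seq experiments built
    around transcribed genomic barcodes: design and validation of DNA
    barcode sets under Hamming-distance and sequence-composition
    constraints, assembly of expression cassettes, demultiplexing of
    cell-by-barcode count matrices (max-count and quantile-threshold
    rules) with transcriptome quality-control filters, repressive
    tendency score (RTS) weighting and the TRIAGE discordance transform,
    density-peak cell typing on two-dimensional embeddings
    (TRIAGE-Cluster), Gaussian-mixture parsing of gene programs over an
    epigenetic reference basis with protein-interaction and term
    enrichment filters (TRIAGE-ParseR), reference-based annotation of
    cells and peaks, and synthetic-data generators that emulate every
    required input so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    cluster,
    jsonlite,
    ape,
    Biostrings,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
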