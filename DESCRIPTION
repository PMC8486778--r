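Package: clonescope
Title: Clonal Copy-Number Inference and Subtype Scoring from Single-Cell
    Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers DNA copy-number profiles from the off-target (outside-peak)
    reads of single-cell ATAC-seq experiments using GC-matched background
    normalization over megabase genome windows, segments the resulting log2
    fold-change profiles with penalized least-squares changepoint detection,
    clusters cells into genetic clones by K-means, calls per-cell epigenetic
    subtypes from promoter accessibility, and scores samples against
    transcription-factor subtype signatures (ASCL1/NEUROD1) with single-sample
    Kolmogorov-Smirnov enrichment statistics. Ships a fully specified synthetic
    data generator with planted copy-number events, GC-dependent coverage bias,
    peak-enriched fragment placement and subtype-structured expression, so the
    whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Matrix,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
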