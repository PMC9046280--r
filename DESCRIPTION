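Package: chromlink
Title: Linking Chromatin Accessibility, Transcription-Factor Motifs, and
    Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of chromatin accessibility (ATAC-seq) and
    transcription-factor binding (ChIP-seq) peak sets with gene expression.
    Implements fractional-overlap peak-set partitioning into shared and
    condition-unique regions, HOMER-style categorical peak annotation,
    transcription-factor motif scanning in peak-center windows with
    cumulative hypergeometric enrichment and rank-differential (waterfall)
    comparison between conditions, distance-based peak-to-gene linking with
    activated/repressed gene classification from expression fold changes,
    median-of-ratios count normalization with per-gene z-transformation,
    gene-signature scoring (z-score-sum and log2-abundance-sum modes),
    cistrome-consensus signature derivation, and hypergeometric
    over-representation analysis. Ships a seeded synthetic-data generator
    that emulates multi-condition peak sets with planted motif occurrences
    and count matrices with planted size factors, regulated genes, and
    signature-positive samples, together with machine-readable truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
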