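Package: pirnadev
Title: piRNA Cluster Expression and Target Analysis Across Postnatal Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for PIWI-interacting RNA (piRNA) populations in
    bulk small RNA-seq of developing tissues: quality-aware read preprocessing
    (quality truncation, barcode and 3' adapter stripping, length gating),
    piRNA-cluster expression calling by read count, RPKM and depth-concentration
    criteria, characterization of candidate piRNA populations (positional base
    composition and 1U bias, read-length modes, cross-sample exact-sequence
    sharing, ncRNA contamination), windowed coverage-correlation profiles along
    clusters, CAGE-based gene expression with power-law tag normalization and a
    transcription-factor expression-scenario filter, and piRNA target prediction
    by top-scoring-hit selection with a Mann-Whitney deadenylation test and by a
    guide/sense complementarity-signature genome scan with repeat-consensus
    filtering. A deterministic synthetic-data module generates a miniature
    genome, annotations, raw reads, truth alignments and CAGE tag tables with
    full ground truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
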