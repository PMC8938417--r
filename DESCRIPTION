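Package: flowreg
Title: Integrative Analysis of Flow-Responsive Regulatory Elements
Version: 0.1.0
Authors@R: person("flowreg", "maintainers", email = "flowreg@example.org",
    role = c("aut", "cre"))
Description: Tools to classify chromatin peaks (H3K27ac ChIP-Seq, ATAC-Seq)
    as gained, lost or common between two conditions, overlap them across
    assays, annotate them to genomic features, associate them with genes
    over basal-plus-extension regulatory domains of up to 1 Mb, cross-
    tabulate associations against differential expression, and score
    transcription-factor motif enrichment with hypergeometric statistics.
    Ships a seeded synthetic-data generator that plants gained/lost/common
    peak structure, correlated expression changes and sequence motifs, and
    a command-line pipeline that runs the full analysis on real or
    synthetic inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    optparse,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
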