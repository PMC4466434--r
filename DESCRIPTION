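Package: repliconflict
Title: Replication-Transcription Conflict Analysis for Bacterial ChIP-Seq,
    qPCR and 2D Gels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies replication fork stalling at transcription units on
    circular bacterial chromosomes. Implements differential ChIP-Seq coverage
    arithmetic (input subtraction, mock-IP correction, between-condition
    differentials), per-region signal quantification, an oriC-aware two-zone
    background model with iterative peak-free window selection, strict
    fold-over-background peak calling, head-on versus co-directional gene
    orientation classification on bidirectionally replicated replichores,
    the ChIP-qPCR double-ratio fold-enrichment statistic, and 2D agarose gel
    Y-arc intensity profiling with 1N-spot loading normalization. A seeded
    synthetic-data generator reproduces the statistical structure of such
    experiments (ori-to-ter copy-number gradient, orientation-dependent
    stalling enrichment, mock-IP stickiness, multinomial fragment sampling)
    so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    tiff,
    rtracklayer,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
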