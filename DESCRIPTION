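Package: degronet
Title: Acute-Degradation Multiomics Integration into Direct Repressor
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates acute-degradation (degron) time-course multiomic
    readouts - bulk RNA-seq, nascent transcription (PRO-seq), chromatin
    accessibility (ATAC-seq) and transcription-factor occupancy (ChIP-seq) -
    into a direct repressor cis-regulatory element (cisRE) / gene network.
    Provides negative-binomial differential testing with volcano
    classification, summit-centered enhancer-RNA quantification from per-base
    density tracks, ChIP/ATAC overlap logic with occupancy-score filtering,
    proximity-based peak-to-gene linking and consensus gene networks, per-cell
    lineage and cisRE accessibility scoring with pseudotime minibulks,
    resampled single-cell differential expression, pre-ranked set enrichment,
    guide- and element-level CRISPR cisRE screen statistics, and small
    estimators (delta-delta-Ct fold change, limiting-dilution frequency).
    A synthetic-data generator plants a known repressor network so every
    stage has a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    SingleCellExperiment,
    Matrix,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
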