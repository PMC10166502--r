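Package: peakscape
Title: Transposable-Element Composition, Enrichment and Expression Analysis
    of Protein-DNA Binding Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates ChIP-seq/CUT&RUN peak calls against RepeatMasker
    repeat tracks, gene models and ENCODE candidate cis-regulatory elements;
    quantifies transposable-element (TE) class and family composition of
    peaks and their fold enrichment relative to genomic coverage ratios;
    scans peak sequences for a binding motif with exact position-weight
    matrix p-values; and quantifies TE expression from multi-mapped
    alignments with random read assignment, followed by a negative-binomial
    Wald test with Benjamini-Hochberg correction, run genome-wide or per
    chromosome. Ships synthetic-data generators with known ground truth for
    every input class so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
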