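Package: aluscape
Title: Genomic Configuration and Transcriptomic Impact of Alu Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genomic arrangement of Alu short
    interspersed elements (SINEs) and its consequences for gene expression.
    Clusters repeat annotations by genomic distance and classifies single,
    tandem and inverted (head-to-head, tail-to-tail) Alu configurations;
    hierarchically partitions the genome (genic/intergenic, exonic/intronic,
    coding/UTR/non-coding) and quantifies proportional "Aluome" coverage and
    enrichment; projects exon-contained Alus into mature-transcript
    coordinates and assigns per-transcript configuration categories; pools
    FPKM expression tables across cell lines and compares configuration
    classes with Wilcoxon rank-sum tests; and designs artificial
    structure-matched UTR analogs by seeded stochastic inverse folding
    against thermodynamic targets. A synthetic-data module generates repeat
    annotations, gene models and expression tables with planted ground truth
    so every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
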