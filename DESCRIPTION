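Package: netscan
Title: Coverage Windowing, Enrichment Screening and Proteomics for
    Neutrophil Extracellular Trap Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of neutrophil extracellular trap (NET)
    genomic sequencing and label-free proteomics. Tiles whole-genome
    coverage into fixed-width windows (20/100/500/5,000 nt), normalizes
    windows per chromosome or genome-wide, screens for windows where one
    sample is at least 1.5-fold enriched or depleted relative to the other
    two, quantifies telomeric repeat content (TTAGGGTTAGGG) and
    mitochondrial DNA enrichment, and compares two-group label-free
    quantification (LFQ) proteomes with a permutation-based false discovery
    rate. A synthetic-data generator produces toy genomes, aligned reads
    with planted copy-number and telomere signal, and LFQ tables with a
    machine-readable truth record for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
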