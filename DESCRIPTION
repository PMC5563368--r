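Package: rhizotox
Title: Integrative Multi-Stress Transcriptome Analysis of Rhizotoxin Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes by their expression pattern across multiple
    rhizotoxic stress treatments (general stress response, uniquely
    regulated, background and low-regulated classes), and characterises the
    resulting classes by permutation-based promoter motif enrichment, intron
    architecture compactness statistics, Nei-Gojobori (NG86) Ka/Ks
    estimation on codon alignments, network hub analysis, and a
    delta-delta-Ct qPCR biomarker specificity screen. Includes a synthetic
    data generator that emulates an eight-stressor, two-timepoint,
    three-replicate microarray design with known ground truth for every
    downstream input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    knitr
Config/testthat/edition: 3
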