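Package: exopair
Title: Strand-Separated ChIP-exo Peak-Pair Mapping of Transcription
    Pre-Initiation Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A base-pair-resolution pipeline for mapping transcription
    pre-initiation complexes (TBP, TFIIB, Pol II) from ChIP-exo data.
    Implements Gaussian-kernel smoothing of strand-separated 5' tag ends
    with an exclusion-zone peak caller, pairing of forward- and
    reverse-strand border peaks into crosslink locations, blacklist and
    tag-count filtering, TSS/CpG-island/genome-segment annotation,
    input-normalized composite profiling, inter-complex distance and
    occupancy statistics, and cross-sample occupancy clustering. A
    synthetic ChIP-exo generator with planted ground truth makes every
    stage testable end-to-end without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    BiocGenerics,
    GenomeInfoDb
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
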