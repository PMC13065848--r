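Package: telofuse
Title: Long-Read Telomere Fusion Amplicon Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of complex chromosomal
    rearrangements in long-read telomere-fusion amplicon sequencing.
    Filters sequencing artefacts and concatemers, labels and trims reads
    by PCR primer, selects an optimal spanning set of split-read
    alignments, types breakpoint junctions (microhomology, blunt,
    insertion/gap), classifies insertion origins and complexity, detects
    10-kb insertion hotspots and foldbacks, and groups reads into unique
    fusion events by graph-based clustering with set-size-dependent
    Jaccard thresholds. Includes a synthetic fusion-event simulator with
    a nanopore-like error model and truth-encoding read identifiers, and
    a precision/recall/F1 benchmarking framework against simulated ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
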