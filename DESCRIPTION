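Package: longscaf
Title: Long-Read Scaffolding of Genome Assembly Contigs with Contig Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders and orients genome assembly contigs into scaffolds using
    long-read (PacBio/Oxford Nanopore) to contig alignments. Alignments are
    coordinate-revised and filtered for reliability, turned into per-read local
    scaffolds, and used to classify contigs as unique or ambiguous (repeat-like).
    A weighted scaffold graph over unique contigs is cleaned by an exact
    orientation program and a position program with big-M slack, leaving only
    simple paths; ambiguous contigs are re-inserted, scaffold ends extended, and
    overlapping scaffolds merged. Includes a simulator that generates synthetic
    genomes, fragmented contig sets with collapsed repeats, and noisy alignment
    records with truth layouts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    igraph,
    pracma,
    jsonlite,
    Biostrings,
    IRanges,
    Rsamtools,
    GenomicAlignments,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
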