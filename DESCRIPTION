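Package: hairpinr
Title: Conservation-Independent miRNA Precursor Discovery from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies plant and algal microRNA precursors from strand-specific
    small RNA sequencing alignments and a reference genome, without relying on
    cross-species sequence conservation. Candidate loci are defined as read
    clusters (expression contigs with gap merging and flank extension), folded
    over a grid of start/stop windows to find the structure minimising the
    per-nucleotide minimum free energy, filtered on secondary-structure
    constraints (terminal loop count, longest double-stranded segment), scored
    for significance against mono-nucleotide shuffle null distributions, and
    verified by read-coverage analysis of mature/star duplexes with the 2-nt
    3' overhang signature of Dicer-like processing. Heterogeneous precursors
    with multiple mature loci are supported. Results are written as BED, GTF,
    CSV and JSON; a synthetic-data generator with ground truth makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
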