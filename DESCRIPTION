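Package: clipindel
Title: Intermediate-Size Indel Detection from Soft-Clipped Short Reads
Version: 0.1.0
Authors@R: person("A.", "Researcher", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects intermediate-size (50 bp to 10,000 bp) insertions and
    deletions from coordinate-sorted short-read alignments. Soft-clipped
    fragments and unmapped reads with mapped mates are clustered at shared
    breakpoints, summarised into consensus fragments by multiple alignment
    with majority voting, joined across the event by a global-in-query
    ("glocal") affine-gap dynamic programming alignment, and compared
    against a local reference window to extract size- and depth-filtered
    indel calls with genotypes. Ships a paired-end read simulator with an
    analytic mapper (aligner-faithful soft-clip CIGARs without an external
    aligner), a greedy k-mer assembler for unmapped reads, and
    precision/recall/F-measure benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
SystemRequirements: MAFFT (optional; only for msa(mode = "external"))
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
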