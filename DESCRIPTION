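Package: valveseq
Title: Pooled Characterization of Transcriptional Valves by Direct RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and characterizing libraries of intrinsic
    transcriptional terminators ("transcriptional valves") with nanopore
    direct RNA sequencing. Enumerates combinatorial spacer-modifier-terminator
    part libraries, simulates error-ridden long reads with ground truth,
    demultiplexes reads to designs by seeded affine-gap local alignment
    against each design's intrinsic barcode, builds nucleotide-resolution
    read-depth and delta profiles, estimates termination efficiency with a
    simulation-based deviation correction, and derives transcript-isoform and
    guide-RNA array stoichiometries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
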