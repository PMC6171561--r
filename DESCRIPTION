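Package: snoclash
Title: CLASH Analysis of Box C/D snoRNA-RNA Interaction Hybrids
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of CLASH (crosslinking, ligation and sequencing of
    hybrids) libraries for box C/D small nucleolar RNAs: demultiplexing and
    PCR-duplicate collapsing of barcoded reads, seed-and-extend chimera
    calling against a custom unspliced-gene reference with snoRNA extension
    and host-gene masking, nearest-neighbour intermolecular duplex folding
    energies, stability and reproducibility filtering with interaction-site
    clustering, classification of snoRNA-target duplexes as 2'-O-methylation
    guide interactions under the +5 rule, positional and gene-feature
    annotation, and over-representation tests of CLASH targets among
    differentially expressed genes. Includes a synthetic CLASH read
    simulator with ground truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
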