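Package: clonetiler
Title: Clone-by-Clone Genome Assembly at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of the clone-by-clone reference
    genome assembly strategy used for BAC-based rice genomes: whole-genome
    profiling (WGP) sequence-tag physical mapping with an FPC-style
    hypergeometric cutoff cascade, minimum-tiling-path selection, BAC pooling,
    pool-assembly circularization with vector excision and clone
    deconvolution, overlap-merge pseudomolecule construction with WGS-contig
    gap bridging, and assembly statistics matching the published table
    semantics. A built-in simulator generates synthetic genomes, HindIII BAC
    libraries, 3D-pooled tag observations, pool unitigs and WGS contigs so the
    whole pipeline is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    IRanges,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
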