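Package: BACmap
Title: BAC Physical Map Construction, Tiling Path Selection, and
    Paired-End Structural Comparison of Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and analysing clone-based physical maps of
    plant-scale genomes. Simulates restriction-enzyme BAC libraries
    (clones, paired end sequences, and restriction fingerprints) from a
    reference genome with assembly gaps and from a rearranged sister
    genome with a known structural-variant truth set. Assembles
    fingerprints into contigs with a Sulston probability-of-coincidence
    score, anchors clones and contigs to a gapped reference using BAC end
    sequences, selects minimum tiling paths per chromosome with a
    shortest-path criterion that minimises clone count and then overlap,
    extends coverage into sequence gaps with unpaired-end clones, and
    classifies paired-end placements into candidate insertions,
    deletions, inversions, and translocations between a query and a
    reference genome, including a genome-flux estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Alignment, Coverage, StructuralVariation,
    GenomeAssembly
RoxygenNote: 7.3.3
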