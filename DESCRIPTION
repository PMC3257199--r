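Package: introgain
Title: Intron Gain Inference in Transposable-Element-Derived Domesticated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers de novo intron gain in gene families whose ancestral state
    is known to be intronless, such as host genes domesticated from the coding
    regions of transposable elements. Extracts and classifies introns from
    per-species gene structures (GFF3/BED12), establishes intron-position
    homology across orthologs by projection through region alignments, places
    gene origins and intron gains onto a named-node species tree by Dollo-style
    parsimony (one gain per homologous site, losses as needed), and computes
    summary statistics: per-node gain tallies, intron densities per kb of CDS
    and 5' UTR, positional bias, size distributions, intron sequence
    conservation, and repeat occupancy. Ships a calibrated forward simulator of
    intron gain/loss on a phylogeny and machine-readable transcriptions of a
    published survey of domesticated-gene intron gains, so that every pipeline
    stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
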