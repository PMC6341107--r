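Package: hijackscan
Title: Detection and Modeling of Enhancer-Hijacking Rearrangements from
    Regulatory Genomics Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for characterizing regulatory
    rearrangements ("enhancer hijacking") in tumor genomes. Turns aligned
    ChIP-seq tags into normalized fragment-density tracks, detects enriched
    regions, stitches and ranks super-enhancers, classifies differential
    regulatory regions between tumor and normal samples, derives consensus
    TAD boundaries from multi-sample Hi-C boundary calls, scans sequence
    with position weight matrices (including oriented CTCF site maps and a
    motif-enrichment test), filters and classifies translocation breakpoints
    into recurrent patterns, reconstructs derived chromosomes reporting
    enhancer-to-TSS distances, and quantifies expression (FPKM/TPM) and
    break-apart FISH cohorts. A synthetic-data module generates every input
    with planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
biocViews: Epigenetics, ChIPSeq, StructuralVariation, GeneRegulation
RoxygenNote: 7.3.3
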