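Package: gametoSNP
Title: SNP Discovery and Clone Identification from Low-Coverage Haploid
    Conifer Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering reliable single nucleotide
    polymorphisms in large repeat-rich conifer genomes from low-coverage
    sequencing of haploid megagametophyte tissue, and for validating the
    resulting marker panel by clone identification. Combines canonical k-mer
    counting with a coverage-band read filter that isolates low-copy genome
    regions, a seed-and-extend mapper with pileup-based haploid variant
    calling and a strict filter cascade, reference-free SNP detection by
    positional clustering on the extended Burrows-Wheeler Transform, contig
    anchoring with coordinate lifting for cross-reference intersection, and
    amplicon genotype calling with mismatch profiles, fuzzy identity
    assignment and a VanRaden genomic relatedness matrix. A fully
    truth-labelled synthetic data generator emulates the study system
    (two gene pools, four ~5x haploid samples, a diverged related-species
    reference, a clonal orchard population) so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stringi,
    yaml,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
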