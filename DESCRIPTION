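Package: pancistrome
Title: Haplotype-Specific TF-Footprint Occupancy, Binding QTL and
    Heritability Partitioning for F1 Hybrid Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of allele-specific
    transcription-factor footprint occupancy in panels of F1 hybrids that
    share a common reference parent. Computes fragment-center coverage
    tracks with reads-per-genome-coverage (RPGC) scaling, binding
    frequencies at biallelic variant sites, footprint polymorphisms (MPs)
    and allele-specific MPs (AMPs) by exact binomial testing with FDR
    control and whole-genome-sequencing control filtering, local
    association mapping of binding QTL (bQTL) with genotype and DNA
    methylation predictors, windowed allelic methylation summaries and
    occupancy concordance, condition-responsive classification of
    allele-specific sites, matched-background SNP sampling, and
    multi-component REML partitioning of trait heritability across
    kinship matrices. A synthetic-data generator reproduces the
    statistical structure of such studies so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
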