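Package: epirate
Title: Region-Level Epimutation Rate Estimation from Bisulfite Data in
    Selfing Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments a plant genome into context-specific cytosine-cluster
    regions (CG, CHG, CHH) by a seed-and-merge algorithm with a 185 bp span
    cap, aggregates whole-genome bisulfite read counts per region, classifies
    regions as unmethylated, intermediate or methylated with a binomial
    mixture model, computes pairwise methylation divergence across
    mutation-accumulation pedigrees, and estimates per-generation methylation
    gain and loss rates (epimutation rates) under neutral and selection
    variants of a three-state selfing Markov inheritance model. Includes a
    fully seeded synthetic-data generator (genomes, annotations, pedigrees,
    methylome evolution, read emission) so that every stage can be validated
    against known ground truth, plus annotation-stratified rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
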