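Package: herdgen
Title: Genomic Management of Small and Fragmented Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the genomic management of small, fragmented livestock
    breeds genotyped on medium-density SNP arrays. Provides PLINK-format
    genotype input/output with marker and sample quality control and LD
    pruning; sliding-window detection of runs of homozygosity (ROH) and
    ROH-based genomic inbreeding coefficients (F_ROH); linkage-disequilibrium
    decay and ancestral effective population size estimation; pedigree
    animal-model BLUP (inbreeding, sparse A-inverse, mixed-model equations,
    EM-REML) with deregression of estimated breeding values; a
    stratification-corrected single-SNP association scan with genomic-control
    adjustment and per-SNP variance explained; and a pedigree/forward
    simulator that generates fully synthetic cohorts with known autozygosity,
    LD history and trait architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
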