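Package: cpgclock
Title: A Vertebrate Lifespan Clock from Promoter CpG Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates vertebrate maximum lifespan from the density of CpG
    dinucleotides in a panel of gene promoters. Builds a species-by-promoter
    CpG-density matrix from genome sequences and promoter homology hits, fits
    an elastic-net regression of log maximum lifespan on promoter densities,
    calibrates the raw scores per vertebrate class with phylogenetic
    generalized least squares under Brownian motion, and applies the resulting
    two-stage clock to new genomes, including extinct species via SNP-edited
    reference loci. Ships a synthetic-panel generator with a planted
    density-lifespan signal so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    ape,
    MASS,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
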