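Package: asecn
Title: Allele-Specific Copy Number and Allele-Specific Expression Calling
    from Paired Tumor WGS and RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls allele-specific copy number (asCN) from tumor whole-genome
    sequencing depth and allele-fraction tables against a reference panel of
    normal samples (depth normalisation, log R ratios, circular binary
    segmentation, five copy-number classes, segment allelic-imbalance
    statistics, integer major/minor state estimation), and tests gene-level
    allele-specific expression (ASE) from RNA-seq allele counts against both
    an equal-expression null and the asCN-derived null, classifying ASE genes
    as CNV-driven or CNV-independent. Includes a synthetic-data generator
    emitting panels, aneuploid tumors with known karyotype and purity, and
    RNA allele counts with injected allelic effects, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    Rcpp,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
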