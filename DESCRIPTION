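Package: qtlfine
Title: Fine-Mapping Toolkit for Recombinant Crosses, Variant Concordance
    Screens, and Permutation-Calibrated Gene-Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-mapping a quantitative trait locus (QTL) with
    recombinant chromosomes and following up the mapped interval at the
    sequence and expression level. Implements covariate-corrected cross
    phenotyping with likelihood-ratio tests of merged genotype-class linear
    models, Mendelian segregation chi-square tests, a filtered variant
    concordance screen (site quality, genotype quality, missingness and
    flank-uniqueness rules, QTL concordance scores, perfect-variant cluster
    reports), and gene-set enrichment on two-group expression matrices using
    per-gene z-scores, one-sample t-tests, Bonferroni correction and an
    empirical permutation null. Ships seeded simulators for crosses, variant
    panels and expression matrices with known planted truth, so every stage
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings,
    vcfR
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
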