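Package: metprime
Title: Comparative Genomic Analysis of Primary and Metastatic Tumour Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for contrasting primary and metastatic
    whole-genome tumour cohorts from per-sample tabular summaries:
    clonal/subclonal mutation classification and cohort clonality
    comparison; arm-level karyotype scoring with whole-genome-duplication
    normalisation and four genomic-instability indicators; mutational
    signature aetiology assignment (reference matching plus hierarchical
    clustering) with absolute, relative and hypermutator exposure
    comparisons; clock-like SBS1 age-regression with bootstrap fits and
    fold-change estimators; a seven-class structural-variant burden model
    with a three-linear-model feature-association screen; and
    treatment-enriched driver detection. Includes a synthetic-cohort
    generator with recorded ground truth so every stage has a
    parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    cluster,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
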