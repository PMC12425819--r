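Package: mutcohort
Title: Power-Gated Comparison of Somatic Mutation Frequencies Between Tumor Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing somatic driver-gene mutation frequencies
    between an exposed and a control tumor cohort when the exposed cohort is
    small. Implements exact Fisher tests with a fixed-margin power gate (the
    minimal achievable P value over all 2x2 tables sharing the observed
    margins), exact conditional stratified tests by hypergeometric convolution,
    Benjamini-Hochberg correction, beta-distribution uncertainty for observed
    frequencies, a TCGA-style molecular-subtype cascade (POLE, MSI, CIN, GS)
    with non-negative least squares signature attribution, cancer-cell-fraction
    clonality and whole-genome-duplication-relative timing, droplet digital PCR
    hotspot calling, background-risk expectation, and a seeded synthetic-cohort
    generator plus MAF/SEG/annotation readers and writers so the whole pipeline
    is testable without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
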