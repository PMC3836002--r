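Package: popfam
Title: Combined Family- and Population-Based Tests of Genetic Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements POPFAM, a nonparametric test of genetic association
    for mixed data sets that contain both case-parent trios and unrelated
    controls. The test is a linear combination of a population-based
    allele-count trend statistic and a family-based Wald statistic of
    Mendelian segregation (equivalent to the transmission disequilibrium
    test), standardized with a closed-form null covariance so that the
    combination is standard normal under no association. Also provides a
    conditional genotype simulator for ascertained trios and controls under
    a two-locus penetrance model with specified linkage disequilibrium,
    orchestration of type-I-error and power studies, a PED/MAP reader and
    per-marker association scans, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
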