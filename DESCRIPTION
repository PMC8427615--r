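Package: msapop
Title: Population Genetic and Epigenetic Analysis of AFLP and
    Methylation-Sensitive AFLP Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for joint analysis of dominant AFLP markers and paired
    HpaII/MspI methylation-sensitive AFLP (MSAP) profiles in structured
    plant populations: methylation-state scoring and classification of
    methylation-susceptible loci, band filtering with duplicate-based
    error rates, POPGENE-style diversity statistics and Nei distance for
    dominant markers, one- and two-level AMOVA with Phi statistics and
    permutation tests, Mantel and partial Mantel tests, FDIST-style
    Fst-outlier scans against a Balding-Nichols neutral envelope,
    univariate logistic environmental association, principal coordinate
    analysis, distance-based linear models with forward selection and
    Storey q-values, UPGMA dendrograms with locus bootstrap, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
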