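Package: cavegrowth
Title: Life-History Analysis of Slow-Growing Fishes: Growth, Ageing
    Precision, Allometry and Energy Storage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative life-history analysis of fishes,
    motivated by slow-growing subterranean loaches. Fits the von
    Bertalanffy growth function by nonlinear least squares with
    per-parameter inference and partitioned (sex and stage) fits;
    fits and tests length-weight allometry including the isometry
    t-test and sex-covariate comparisons; computes age-reading
    precision indices (average percent error and average coefficient
    of variation) and otolith-versus-vertebra agreement; compares
    growth performance (phi-prime) across species on auximetric axes
    with ordinary and phylogenetic generalized least squares (Pagel's
    lambda, maximum likelihood); computes tissue energy density from
    proximate composition; and ships a seeded synthetic-cohort
    generator so every stage is testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    MASS,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
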