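Package: flockconnect
Title: Genetic Connectedness Diagnostics from the Fixed-Effect Variance Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes genetic connectedness diagnostics between contemporary
    groups in single-trait animal-model BLUP evaluations. The contemporary-group
    averaged prediction error variance-covariance matrix (PEVMean) is obtained
    exactly from the variance-covariance matrix of estimated fixed effects
    alone, avoiding the random-effect block of the mixed model equation inverse.
    Includes pedigree numerator relationship matrices and their sparse inverses
    (Meuwissen-Luo), genomic relationship matrices (VanRaden method 1),
    single-step H-inverse construction (Aguilar), Henderson mixed model
    equations with block solving, the full family of pairwise connectedness
    statistics (PEVD, flock correlation, VED, corrected VED, connectedness
    rating, coefficient of determination of contrasts), model diagnostics
    (correction-factor trace, covariance ratio, mixed-model r-squared), and a
    synthetic multi-flock data simulator with gene-dropped genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
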