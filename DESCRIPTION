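Package: mrmediate
Title: Two-Sample Mendelian Randomization and Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    and two-step mediation analysis from GWAS summary statistics, built for
    exposure -> mediator -> outcome designs such as gut microbiota ->
    circulating metabolite -> disease. Provides summary-statistics input and
    output with configurable column maps, instrument selection with greedy
    linkage-disequilibrium clumping and F-statistic strength filtering, allele
    harmonization with palindromic-variant exclusion and strand recovery, the
    inverse-variance-weighted, MR-Egger and weighted-median estimators,
    sensitivity diagnostics (Cochran's Q, Egger intercept, leave-one-out,
    MR-PRESSO), product-of-coefficients effect decomposition with mediator
    screening, Benjamini-Hochberg false discovery control, and a synthetic
    summary-statistics generator with planted causal structure for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
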