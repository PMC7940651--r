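Package: transherit
Title: Hybrid Heritability Decomposition with Transmitted Parental Environment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing liability-scale heritability of binary
    disorders under a hybrid model in which a fraction x of the couple-shared
    parental environmental variance is transmitted to offspring alongside
    additive genetic variance. Provides the closed-form solver for the hybrid
    model, reproduction of published per-disorder decompositions from summary
    statistics, a nuclear-family liability-threshold simulator implementing the
    transmission model, maximum-likelihood tetrachoric correlations for spouse,
    parent-offspring and sibling pairs, and variance-component recovery that
    contrasts naive and hybrid heritability estimators.
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
    utils,
    withr
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
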