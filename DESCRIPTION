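Package: poweraudit
Title: Power and Equivalence Auditing of Meta-Analysis Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Audits the evidential value of a collection of meta-analyses of
    standardized mean differences. Computes per-study statistical power under a
    two-sided Wald test across a grid of assumed true effects and at the
    observed summary estimate, runs two one-sided (TOST) equivalence tests of
    summary effects against smallest-effect-size-of-interest bounds, forms
    Welch contrasts and two-sample equivalence tests from subgroup summary
    statistics, applies the Ioannidis-Trikalinos Test of Excess Significance to
    univariate meta-analyses, and profiles power over publication years. A
    random-effects corpus simulator with an optional significance-censoring
    (publication-bias) mechanism makes the whole pipeline runnable and
    calibratable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tibble,
    tidyr
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
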