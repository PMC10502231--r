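Package: clonesig
Title: Drug-Response Heterogeneity and Consensus Protein Signatures for
    Single Cell-Derived Clones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling treatment-response heterogeneity among
    single cell-derived clonal cell lines (SCDCLs): normalization of
    viability assays to untreated controls, four-parameter logistic
    dose-response fitting with bootstrap IC50 confidence intervals and
    ICmax extraction, population-doubling-time estimation from cell
    counts, two-strata responder stratification, and a seeded ensemble of
    random-forest regressions with backward feature elimination that
    extracts consensus protein signatures associated with treatment
    response via a rank-based scoring scheme. Includes a synthetic-data
    module that simulates viability plates, growth curves, and DIA-style
    protein intensity matrices with planted response-associated proteins
    for validation.
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
    jsonlite,
    minpack.lm,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
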