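Package: pvsignal
Title: Pharmacovigilance Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for disproportionality analysis of
    FAERS-style spontaneous adverse-event reports: reading and cleaning the
    quarterly "$"-delimited ASCII tables (merge, deletion-list purge,
    case-version deduplication, demographic/drug/reaction joins), building
    fourfold contingency tables at MedDRA preferred-term and system-organ-class
    level, screening signals with four algorithms (reporting odds ratio,
    proportional reporting ratio with chi-square, BCPNN information component,
    and a closed-form EBGM), Weibull time-to-onset modelling, subgroup and
    reporting-period comparisons, and covariate-adjusted reporting odds ratios
    via an internally fitted logistic model. Ships a synthetic FAERS-like
    report generator with known ground truth so every stage is testable
    without a database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
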