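Package: pyroclock
Title: Evaluation of Small-Panel Pyrosequencing Epigenetic Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to apply and evaluate small-panel CpG-methylation
    epigenetic clocks of the kind read out by targeted pyrosequencing
    (two- to four-site age predictors). Provides validated readers for
    per-sample methylation tables and clock-coefficient configurations,
    per-site regressions of methylation on age, the standard accuracy
    statistics for age predictors (mean absolute deviation, standard
    error of the estimate, percent of correct predictions, squared
    correlation), age-group and sex-stratified evaluation with rank-sum
    comparisons of delta age, error dynamics across cumulative age
    ranges, and a calibrated synthetic-cohort generator so the whole
    pipeline can be exercised and tested without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
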