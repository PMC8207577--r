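Package: edies
Title: Emergency Department Severity Scoring and Standardized W Statistics
Version: 0.1.0
Authors@R: person("EDIES", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the Emergency Department Initial Evaluation Score
    (EDIES), an integer point score summing eight items (sex, cause of visit,
    AVPU consciousness level, age, systolic blood pressure, heart rate,
    respiratory rate, pulse oximetry) recorded at ED arrival, together with
    the W and standardized W (Ws) statistics for severity-adjusted mortality
    benchmarking of an ED cohort against a reference population. Includes
    cohort input/output with an auditable exclusion cascade, rebuilding of
    integer score tables from logistic-regression coefficients, confidence
    intervals for Ws, severity-reweighted resampling experiments that measure
    the empirical coverage of those intervals, and a synthetic cohort
    generator so the whole pipeline is testable without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
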