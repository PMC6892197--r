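Package: sacekit
Title: Survivor Average Causal Effect Estimation with Outcomes Truncated by
    Death and Missing by Non-Attendance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the survivor average causal effect (SACE) of a
    binary exposure on a binary outcome when outcomes are truncated by death
    and further missing because surviving participants do not attend
    follow-up. Implements a marginal structural model with stabilized
    inverse-probability weights for exposure, survival and attendance, and a
    closed-form principal-stratification sensitivity analysis indexed by the
    ratio of outcome odds between compliant-survivors and always-survivors.
    Includes a principal-strata cohort simulator calibrated to a target SACE
    odds ratio, bias-corrected bootstrap confidence intervals, covariate
    balance diagnostics, and a Monte-Carlo study harness that evaluates both
    estimators over a factorial grid of unmeasured-confounding scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
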