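Package: liferisk
Title: Lifetime Risk of Surgery from Stratified Registry Counts
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the lifetime risk of an event (here, surgery) from
    age-band and sex stratified registry counts: annual event, mid-year
    population and all-cause death tables. Implements the competing-risk
    abridged life-table estimator and the cumulative-incidence estimator,
    multi-year averaging with t-based confidence intervals, parametric
    bootstrap intervals for single years, and a paired comparison of a
    pre-pandemic against a pandemic period. Includes a synthetic registry
    generator with piecewise-constant hazards and analytic ground truth
    for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
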