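Package: mcbscore
Title: ESMO-MCBS Clinical Benefit Grading for Recurrent Ovarian Cancer Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the European Society for Medical Oncology Magnitude of
    Clinical Benefit Scale (ESMO-MCBS) grading procedure for palliative-intent
    randomised trials in recurrent epithelial ovarian cancer. Trial summary
    records (control-arm medians, absolute gains, hazard ratios with 95%
    confidence intervals, response rates, quality-of-life and toxicity
    evidence flags) are screened for eligibility, assigned an evaluation form
    (2a, 2b, 2c or 3) from the primary endpoint and control-arm survival,
    graded against the form's hazard-ratio lower-bound and absolute-gain
    thresholds, adjusted by at most one grade for quality-of-life or toxicity
    evidence, and reported with a full rule-firing rationale. Includes a
    curated corpus of published trial rows, a comparator benefit-network
    builder, and a seeded synthetic trial generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
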