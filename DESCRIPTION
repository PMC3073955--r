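Package: hedisim
Title: Markov Cohort Models for the Employer Business Case of Reducing
    Quality-of-Care Disparities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov cohort models, with an individual-level
    Monte-Carlo validation simulator, for quantifying the employer-facing
    consequences of closing racial/ethnic gaps in two HEDIS quality
    measures: the two-year mammography screening rate in employed women
    aged 50-65 (annual cycles over five years, stage-shift at diagnosis)
    and the appropriate asthma controller-medication rate in adults and
    children (monthly cycles over up to five years, exacerbation states).
    State occupancy is propagated by expectation and multiplied by
    per-cycle rewards on independent channels (quality-adjusted life,
    survival, employment, work/school days, direct medical cost), with
    one-off transition rewards for within-cycle events such as cancer
    treatment. Companion functions convert day and event channels into
    absenteeism and turnover money, assemble business-case comparison
    tables, and drive scenario and stage-distribution sensitivity
    analyses. Parameter sets load from annotated YAML configuration
    files; a small command-line interface wraps the main entry points.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
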