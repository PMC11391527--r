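Package: hipcea
Title: Cost-Effectiveness of Hemiarthroplasty Versus Internal Fixation for
    Femoral Neck Fracture
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing
    hemiarthroplasty (HA) and internal fixation (IF) for nondisplaced femoral
    neck fracture in elderly patients. Implements a five-state Markov cohort
    model with conversion-to-arthroplasty failure pathways run over an annual
    cycle, discounted cost and quality-adjusted life-year (QALY) accumulation,
    incremental cost-effectiveness ratio (ICER) and dominance classification,
    one-way (tornado), two-way and threshold sensitivity analyses, and Monte
    Carlo probabilistic sensitivity analysis with method-of-moments
    Beta/Gamma parameter distributions, cost-effectiveness plane summaries and
    acceptability curves. An independent patient-level microsimulation is
    included to validate the cohort engine, together with generators for
    synthetic life tables and parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
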