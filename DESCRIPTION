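Package: catiqc
Title: Quality-Control Indicator Engine for CATI Survey Paradata
Version: 0.1.0
Authors@R:
    person("SESRI", "QC Tools", email = "qc-tools@example.org", role = c("aut", "cre"))
Description: Computes interviewer quality-control indicators from telephone-survey
    paradata: keystroke audit trails are reconstructed into per-question field
    visits and interview timelines; case-level flags (short/long question field
    times, multiple field visits, interview-length and negative-stem checks) and
    two-week interviewer-window z-score flags (disorder prevalence, short average
    interview length) are evaluated against a single threshold configuration;
    verification metrics (monitoring coverage, dials and completes per hour,
    reported-time discrepancies) are derived from call detail records and
    interviewer time logs.  Includes a seeded synthetic-paradata simulator with
    configurable interviewer archetypes, flag-summary and monitoring-coverage
    reporting, a prioritized investigation task queue, and a batch command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
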