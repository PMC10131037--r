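Package: rhythmkit
Title: Cosinor Rhythmometry and Circadian Group Comparison for Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 24-hour rhythms in case-control biomarker
    studies: single-component cosinor fitting with zero-amplitude F tests and
    circular acrophase statistics; two-stage multivariate random-effects
    pooling of per-subject rhythm parameters with log-scale back-transformation;
    detection-limit substitution and circadian-variation (maximum/minimum)
    summaries; Firth penalized logistic regression; nocturnal dipper
    classification of ambulatory blood-pressure and heart-rate profiles; and
    delta-Ct cosinor comparison of clock-gene expression in animal models.
    Includes seeded synthetic-cohort generators emulating 7-time-point hormone
    sampling and zeitgeber-time qPCR panels, and pipeline drivers that chain
    the stages into reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    Matrix,
    jsonlite,
    knitr
Config/testthat/edition: 3
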