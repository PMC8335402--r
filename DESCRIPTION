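Package: hrvfatigue
Title: Fatigue Quadrant Classification from Heart Rate Variability and
    Stroop Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores mental-fatigue state from two smartphone-grade
    measurements: time-domain heart rate variability (AVNN, SDNN, RMSSD,
    pNN50, heart rate) with a Baevsky-type stress index computed from
    RR-interval series, and mean reaction time on a 35-stimulus Stroop
    task. Observed SDNN is compared against an age-referenced normative
    value; the SDNN deviation and a 500 ms reaction-time cutoff jointly
    place each session into one of four fatigue quadrants. A from-scratch
    multinomial logistic classifier (reference-category parameterization,
    Newton iteration with optional ridge) models quadrant membership from
    physiological and lifestyle covariates, reporting odds ratios, Wald
    tests, Nagelkerke pseudo-R-squared and a classification table. A
    seeded synthetic cohort generator makes the full pipeline runnable
    and testable without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
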