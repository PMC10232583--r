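Package: csurv
Title: Cohort Data Harmonisation with the C-Surv Data Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A schema-driven engine for harmonising participant-level data
    from diverse population cohorts to a common target data model (C-Surv).
    Provides a machine-readable 124-variable core schema organised into 18
    data themes, three harmonisation strategies (simple calibration,
    algorithmic transformation, and z-score standardisation with a
    skew-conditional natural-log transform), per-cohort mapping rules
    (codebook recodes, binary inference from diagnosis dates and symptom
    scores, date truncation, unit conversion, within-cohort income
    quantiles), and coverage analytics (theme coverage, cross-cohort
    overlap distributions, strategy tallies and correspondence summaries)
    that quantify the harmonisation potential of a set of cohorts.
    Includes a deterministic synthetic-cohort generator emulating four
    diverse studies with their native codings, so the full pipeline is
    testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
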