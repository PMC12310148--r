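Package: wearcomply
Title: Wear-Time Compliance Analysis for Consumer Wearable Studies
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for feasibility and acceptability analysis of
    consumer-wearable (Fitbit-style) deployments in clinical cohorts.
    Simulates minute-epoch heart-rate and step streams with realistic
    artifacts (charging gaps, clip-mode sensor dropout, on-device storage
    truncation), parses raw JSON exports into validated epoch tables,
    infers per-minute wear time from sensor-data presence, classifies
    day and night compliance against configurable thresholds (600 daytime
    minutes; 180 continuous minutes within sleep), raises study-monitoring
    flags for sync lapses and noncompliance streaks, and computes group
    summary statistics with pooled t tests and Mann-Whitney U tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
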