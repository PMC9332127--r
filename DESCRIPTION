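Package: calorchamber
Title: Whole-Room Indirect Calorimetry Energy Expenditure Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing 24-hour whole-room indirect calorimetry
    (respiration chamber) studies in humans. Converts minute-resolution
    oxygen consumption, carbon dioxide production and urinary nitrogen into
    energy expenditure and substrate oxidation (Brouwer and Weir
    stoichiometry), partitions the 24-h day into sleeping and resting
    metabolic rate, sedentary energy expenditure, diet-induced
    thermogenesis, exercise and spontaneous activity components via
    sliding-window detectors and the activity-intercept regression method,
    estimates free-living energy expenditure from wrist accelerometer
    counts anchored to chamber resting metabolic rate, and analyses
    two-arm intervention cohorts with baseline-adjusted change-score
    ANCOVA, outlier screening and partial correlation. A synthetic chamber
    and cohort simulator with exact ground-truth component ledgers supports
    end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
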