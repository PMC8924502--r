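Package: harvestplan
Title: Planting Schedules from Growing Degree Unit Forecasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A two-stage decision-support toolkit for seed-corn planting.
    Stage one forecasts daily growing degree units (GDUs) over a 1.5-year
    horizon with a one-dimensional convolutional network trained on sliding
    two-year windows, benchmarked against a pluggable seasonal forecaster.
    Stage two converts planting windows and per-population GDU requirements
    into harvest-week eligibility and solves mixed-integer linear programs
    that schedule planting so weekly harvest totals respect storage capacity
    while using a minimum number of harvesting weeks, for both fixed and
    flexible capacity. Includes seeded synthetic-data generators, schedule
    evaluation metrics, CSV/JSON input-output, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: python (>= 3.8) with scipy (>= 1.9) on PATH, used by the
    MILP solver backend.
Config/testthat/edition: 3
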