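Package: bedbench
Title: Hospital Bed-Management Indicators and Regional Efficiency Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking regional hospital capacity and inpatient
    activity. Computes the four classical bed-management indicators (bed
    occupancy rate, average length of stay, turnover interval, bed turnover)
    from bed stocks and discharge activity, classifies regions into
    Barber-Johnson efficiency zones, and scores case complexity and length-of-
    stay performance with AvLOS-based Case-Mix and Performance indices against
    a pooled multi-region benchmark. Includes a reader/writer for Eurostat
    bulk-download TSV extracts at NUTS-2 level, cross-region dispersion
    summaries (percent change, per-100k rates, coefficient of variation), and
    a seeded synthetic-panel generator with ground-truth zone and quadrant
    labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
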