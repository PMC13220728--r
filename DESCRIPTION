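Package: dielrate
Title: Exposure-Adjusted Time-of-Day Analysis of Record Rates in Competition Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying diel (time-of-day) structure in the probability
    of record-setting performances at scheduled competitions. Converts UTC round
    start times to local civil time with the IANA timezone database, discretises
    them into quarter-hour bins, expresses record counts per attempt within each
    bin (exposure adjustment), and evaluates non-uniformity and a post-prandial
    window contrast against a within-competition permutation null that preserves
    the observed schedule and attempt structure. Includes readers for a
    documented competition-results table dialect and a schedule JSON subset,
    stratified sensitivity analyses, and a seedable synthetic-data generator
    that emulates non-uniform scheduling and an optional local-time dip in
    record probability.
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
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
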