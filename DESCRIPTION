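Package: flamingr
Title: Citizen-Science Occurrence-Record Analysis for the American Flamingo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing citizen-science
    occurrence records of the American Flamingo (Phoenicopterus ruber) in an
    eBird-Basic-Dataset-like layout. Implements geographic scoping,
    one-record-per-location-per-day deduplication and quantitative-count
    filtering with full record accounting; per-country and per-decade
    summaries; observer-effort indices (record days, individuals per record);
    breeding-season importance percentages with a reference-site threshold
    for flagging critical potential breeding countries; classification of
    records against a recognized range polygon; and a seeded synthetic-data
    generator (including an exact-accounting mode) so every stage is testable
    without any download.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
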