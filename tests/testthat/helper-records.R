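# Quick occurrence-record constructor with sensible Caribbean defaults.
make_records <- function(record_id,
                         country = "Cuba",
                         subnational = "",
                         locality_id = "",
                         latitude = 21.5,
                         longitude = -78.0,
                         date = as.Date("2015-06-01"),
                         count = 1L) {
  tibble::tibble(
    record_id = record_id, country = country, subnational = subnational,
    locality_id = locality_id, latitude = latitude, longitude = longitude,
    date = as.Date(date), count = as.integer(count)
  )
}

# Write a TSV in the default eBird dialect from raw cell rows.
write_ebird_tsv <- function(rows, path) {
  header <- paste(unname(ebird_dialect()), collapse = "\t")
  writeLines(c(header, vapply(rows, paste, "", collapse = "\t")), path)
  path
}

unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

# Plain data-frame view of a records tibble, with the bookkeeping
# attributes (removed rows, validation report) stripped for comparisons.
strip_tbl <- function(x) {
  attr(x, "flam_removed") <- NULL
  attr(x, "flam_problems") <- NULL
  as.data.frame(x)
}

# A small, structurally varied random dataset for property-style tests.
random_dataset <- function(seed) {
  cfg <- synthetic_config(
    effort = c("1990s" = 20, "2000s" = 40, "2010s" = 80),
    duplicate_prob = 0.3, presence_only_prob = 0.15,
    out_of_scope_count = 5, seed = seed
  )
  generate_occurrences(cfg)
}
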