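#' Column-name dialect for eBird-Basic-Dataset-like TSV files
#'
#' Maps the occurrence-record fields used throughout the package onto the
#' column headers of a tab-separated extract. The default matches the eBird
#' Basic Dataset headers; any field can be remapped for other providers.
#'
#' @param record_id,country,subnational,locality_id,latitude,longitude,date,count
#'   Header names for the corresponding record fields.
#' @return A named character vector with one entry per record field.
#' @examples
#' ebird_dialect()
#' ebird_dialect(country = "NATION")
#' @seealso [read_records()], [write_records()]
#' @export
ebird_dialect <- function(record_id = "SAMPLING EVENT IDENTIFIER",
                          country = "COUNTRY",
                          subnational = "STATE/PROVINCE",
                          locality_id = "LOCALITY ID",
                          latitude = "LATITUDE",
                          longitude = "LONGITUDE",
                          date = "OBSERVATION DATE",
                          count = "OBSERVATION COUNT") {
  c(
    record_id = record_id, country = country, subnational = subnational,
    locality_id = locality_id, latitude = latitude, longitude = longitude,
    date = date, count = count
  )
}

record_fields <- c(
  "record_id", "country", "subnational", "locality_id",
  "latitude", "longitude", "date", "count"
)

#' Parse an observation-count token
#'
#' eBird reports either a positive integer number of individuals or the
#' presence-only marker `"X"` (the species was seen but not counted).
#' Presence-only is represented as `NA_integer_` throughout the package;
#' the quantitative filter removes such records.
#'
#' @param token Character vector of count tokens.
#' @return Integer vector; `NA` encodes presence-only.
#'   Zero, negative, fractional or non-numeric tokens are an error: a sighting
#'   of zero birds is not a record.
#' @examples
#' parse_count(c("150", "X", "2"))
#' @export
parse_count <- function(token) {
  parsed <- parse_count_quietly(token)
  bad <- !is.na(parsed$reason)
  if (any(bad)) {
    stop(
      "invalid count token(s): ",
      paste(unique(token[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  parsed$count
}

# Vectorized count parser that reports, instead of raising, per-token
# failures; the reader uses it to skip bad rows with a logged reason.
parse_count_quietly <- function(token) {
  token <- trimws(as.character(token))
  n <- length(token)
  count <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)

  is_x <- !is.na(token) & toupper(token) == "X"
  is_int <- !is.na(token) & grepl("^[0-9]+$", token)

  suppressWarnings(val <- as.numeric(token[is_int]))
  ok_int <- is_int
  ok_int[is_int] <- !is.na(val) & val >= 1 & val <= .Machine$integer.max
  count[ok_int] <- as.integer(as.numeric(token[ok_int]))

  bad <- !(is_x | ok_int)
  reason[bad] <- ifelse(
    is.na(token[bad]) | token[bad] == "",
    "empty count token",
    paste0("invalid count token '", token[bad], "'")
  )
  list(count = count, reason = reason)
}

serialize_count <- function(count) {
  ifelse(is.na(count), "X", format(count, scientific = FALSE, trim = TRUE))
}

#' Read occurrence records from a TSV extract
#'
#' Reads a tab-separated, UTF-8 file with a header row and returns one
#' occurrence record per valid data row, in file order. Rows that fail
#' validation (unparseable date or coordinate, coordinate out of range,
#' invalid count token, missing or duplicated record identifier) are skipped,
#' and each skipped row is reported as a line `"<line-number>: <reason>"`
#' retrievable with [validation_report()]. Citizen-science extracts are
#' dirty; the cleaning philosophy is discard, not repair.
#'
#' @param path Path to a TSV file whose header contains every column named in
#'   `dialect`; a missing mapped column is a fatal format error.
#' @param dialect Column-name mapping, see [ebird_dialect()].
#' @return A tibble with columns `record_id`, `country`, `subnational`,
#'   `locality_id`, `latitude`, `longitude`, `date` (class `Date`) and
#'   `count` (integer, `NA` = presence-only), carrying the validation report
#'   as an attribute.
#' @examples
#' tsv <- tempfile(fileext = ".txt")
#' recs <- generate_occurrences(synthetic_config(seed = 7))
#' write_records(recs, tsv)
#' again <- read_records(tsv)
#' nrow(again) == nrow(recs)
#' @export
read_records <- function(path, dialect = ebird_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(all(record_fields %in% names(dialect)))

  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  missing <- setdiff(unname(dialect[record_fields]), names(raw))
  if (length(missing) > 0) {
    stop(
      "missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }

  out <- tibble::tibble(
    record_id = raw[[dialect[["record_id"]]]],
    country = raw[[dialect[["country"]]]],
    subnational = raw[[dialect[["subnational"]]]],
    locality_id = raw[[dialect[["locality_id"]]]],
    latitude = suppressWarnings(as.numeric(raw[[dialect[["latitude"]]]])),
    longitude = suppressWarnings(as.numeric(raw[[dialect[["longitude"]]]])),
    date = as.Date(raw[[dialect[["date"]]]], format = "%Y-%m-%d"),
    count_token = raw[[dialect[["count"]]]]
  )

  parsed <- parse_count_quietly(out$count_token)
  reason <- parsed$reason
  reason[is.na(reason) & is.na(out$date)] <- "unparseable date"
  reason[is.na(reason) & (is.na(out$latitude) | abs(out$latitude) > 90)] <-
    "latitude missing or outside [-90, 90]"
  reason[is.na(reason) & (is.na(out$longitude) | abs(out$longitude) > 180)] <-
    "longitude missing or outside [-180, 180]"
  reason[is.na(reason) & (is.na(out$record_id) | out$record_id == "")] <-
    "missing record_id"
  dup <- duplicated(out$record_id)
  reason[is.na(reason) & dup] <- "duplicate record_id"

  keep <- is.na(reason)
  records <- out[keep, ]
  records$count <- parsed$count[keep]
  records$count_token <- NULL
  records$subnational[is.na(records$subnational)] <- ""
  records$locality_id[is.na(records$locality_id)] <- ""

  problems <- tibble::tibble(
    line = which(!keep) + 1L, # header occupies line 1
    reason = reason[!keep]
  )
  if (nrow(problems) > 0) {
    message(
      nrow(problems), " row(s) skipped during validation; ",
      "see validation_report()"
    )
  }
  attr(records, "flam_problems") <- problems
  records
}

#' Validation report of a read
#'
#' @param records A tibble returned by [read_records()].
#' @return Character vector of `"<line-number>: <reason>"` lines, empty when
#'   every row validated.
#' @export
validation_report <- function(records) {
  problems <- attr(records, "flam_problems")
  if (is.null(problems) || nrow(problems) == 0) return(character())
  paste0(problems$line, ": ", problems$reason)
}

#' Write occurrence records to a TSV file
#'
#' Serializes records in the same dialect that [read_records()] consumes, so
#' the write/read composition is the identity on valid data. Presence-only
#' counts are written back as the token `"X"`.
#'
#' @param records Occurrence-record tibble (see [read_records()]).
#' @param path Output file path.
#' @param dialect Column-name mapping, see [ebird_dialect()].
#' @return The path, invisibly.
#' @export
write_records <- function(records, path, dialect = ebird_dialect()) {
  validate_records(records)
  out <- tibble::tibble(
    a = records$record_id,
    b = records$country,
    c = records$subnational,
    d = records$locality_id,
    e = sprintf("%.6f", records$latitude),
    f = sprintf("%.6f", records$longitude),
    g = format(records$date, "%Y-%m-%d"),
    h = serialize_count(records$count)
  )
  names(out) <- unname(dialect[record_fields])
  write_atomically(function(tmp) {
    readr::write_tsv(out, tmp, progress = FALSE)
  }, path)
}

# Structural validity shared by every pipeline stage.
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(record_fields, names(records))
  if (length(missing) > 0) {
    stop(
      "records are missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(records) == 0) return(invisible(records))
  stopifnot(
    all(abs(records$latitude) <= 90),
    all(abs(records$longitude) <= 180),
    inherits(records$date, "Date"),
    all(is.na(records$count) | records$count >= 1)
  )
  if (anyDuplicated(records$record_id)) {
    stop("record_id values must be unique", call. = FALSE)
  }
  invisible(records)
}
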