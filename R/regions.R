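#' Build a region scheme
#'
#' A region scheme carries everything needed to place a record geographically:
#' a country-to-region mapping, optional sub-country splits (tested by
#' subnational code first, polygon fallback), and the recognized-distribution
#' polygon used for inside/outside classification.
#'
#' @param country_to_region Named character vector: country name to region
#'   name.
#' @param subcountry_rules Named list, one entry per split country. Each entry
#'   is itself a named list of units; a unit is a character vector of
#'   subnational codes, a list with elements `codes` and/or `polygon`
#'   (a `(longitude, latitude)` matrix), or `NULL` marking the catch-all unit
#'   that makes the split exhaustive.
#' @param recognized_range Polygon or multipolygon of the recognized
#'   distribution.
#' @return A `flam_scheme` object.
#' @seealso [default_region_scheme()]
#' @export
region_scheme <- function(country_to_region,
                          subcountry_rules = list(),
                          recognized_range = recognized_range_polygon()) {
  stopifnot(
    is.character(country_to_region), !is.null(names(country_to_region)),
    is.list(subcountry_rules)
  )
  if (anyDuplicated(names(country_to_region))) {
    stop("each country must map to exactly one region", call. = FALSE)
  }
  structure(
    list(
      country_to_region = country_to_region,
      subcountry_rules = subcountry_rules,
      recognized_range = as_rings(recognized_range)
    ),
    class = "flam_scheme"
  )
}

#' @export
print.flam_scheme <- function(x, ...) {
  cat("<flam_scheme>\n")
  cat(
    "  countries:",
    length(x$country_to_region), "in",
    length(unique(x$country_to_region)), "regions\n"
  )
  cat("  sub-country splits:", paste(names(x$subcountry_rules), collapse = ", "), "\n")
  cat("  recognized range:", length(x$recognized_range), "ring(s)\n")
  invisible(x)
}

#' The default region scheme for the American Flamingo assessment
#'
#' Thirty-two countries and territories of the Americas mapped onto four
#' regions — North America, Central America, South America and the Caribbean —
#' following the convention of continental flamingo assessments (note that
#' Bonaire and Curacao are grouped with South America while Aruba sits in the
#' Caribbean). Two countries are split into sub-country units: Mexico into
#' the Yucatan Peninsula (Yucatan, Campeche, Quintana Roo) and Central
#' Mexico, and the USA into the Gulf of Mexico/Florida coast (Florida,
#' Alabama, Mississippi, Louisiana, Texas) and the East and West Coast.
#' Membership lists are plain data and can be edited on the returned object.
#'
#' @param recognized_range Recognized-distribution polygon; defaults to the
#'   coarse synthetic polygon shipped with the package.
#' @return A `flam_scheme` object.
#' @export
default_region_scheme <- function(recognized_range = recognized_range_polygon()) {
  north <- c("Bermuda", "Canada", "USA", "Mexico")
  central <- c("Belize", "Honduras")
  south <- c(
    "Bonaire", "Brazil", "Colombia", "Cura\u00e7ao", "Ecuador",
    "Guyana", "Suriname", "Venezuela"
  )
  caribbean <- c(
    "Anguilla", "Aruba", "Bahamas", "Barbados", "Cayman Island", "Cuba",
    "Dominican Republic", "Granada", "Guadalupe", "Haiti", "Jamaica",
    "Puerto Rico", "Saint Kitts", "Saint Martin", "Trinidad and Tobago",
    "Turks and Caicos Islands", "Virgin Island"
  )
  country_to_region <- c(
    stats::setNames(rep("North America", length(north)), north),
    stats::setNames(rep("Central America", length(central)), central),
    stats::setNames(rep("South America", length(south)), south),
    stats::setNames(rep("Caribbean", length(caribbean)), caribbean)
  )
  subcountry_rules <- list(
    Mexico = list(
      "Mexico-Yucatan Peninsula" = c(
        "Yucat\u00e1n", "Yucatan", "Campeche", "Quintana Roo"
      ),
      "Mexico-Central" = NULL
    ),
    USA = list(
      "US-Gulf of Mexico/Florida" = c(
        "Florida", "Alabama", "Mississippi", "Louisiana", "Texas"
      ),
      "US-East and West Coast" = NULL
    )
  )
  region_scheme(country_to_region, subcountry_rules, recognized_range)
}

# Resolve the sub-country unit for one country's records.
resolve_subcountry <- function(records, country, rules) {
  unit <- rep(NA_character_, nrow(records))
  catch_all <- NA_character_
  for (unit_name in names(rules)) {
    spec <- rules[[unit_name]]
    if (is.null(spec)) {
      catch_all <- unit_name
      next
    }
    codes <- if (is.list(spec)) spec$codes else spec
    hit <- rep(FALSE, nrow(records))
    if (!is.null(codes)) hit <- records$subnational %in% codes
    if (is.list(spec) && !is.null(spec$polygon)) {
      hit <- hit | point_in_polygon(
        records$longitude, records$latitude, spec$polygon
      )
    }
    unit[is.na(unit) & hit] <- unit_name
  }
  unit[is.na(unit)] <- if (!is.na(catch_all)) catch_all else country
  unit
}

#' Assign records to regions and units
#'
#' Adds a `region` column, and a `unit` column naming the finest geographic
#' unit: the sub-country unit for split countries, the country otherwise.
#' Countries absent from the scheme are routed to the explicit
#' `"Unassigned"` region (never silently dropped) and reported via a message.
#'
#' @param records Occurrence-record tibble.
#' @param scheme A `flam_scheme`, see [default_region_scheme()].
#' @return The records with `region`, `unit` columns added.
#' @export
assign_region <- function(records, scheme = default_region_scheme()) {
  validate_records(records)
  region <- unname(scheme$country_to_region[records$country])
  n_unknown <- sum(is.na(region))
  if (n_unknown > 0) {
    message(
      n_unknown, " record(s) from countries outside the scheme ",
      "assigned to region 'Unassigned'"
    )
    region[is.na(region)] <- "Unassigned"
  }
  unit <- records$country
  for (country in intersect(names(scheme$subcountry_rules), records$country)) {
    idx <- which(records$country == country)
    unit[idx] <- resolve_subcountry(
      records[idx, ], country, scheme$subcountry_rules[[country]]
    )
  }
  dplyr::mutate(records, region = region, unit = unit)
}

#' Decade label of observation dates
#'
#' Dates are binned into decades `"1960s"` through `"2010s"`; the analysis
#' window runs from 1960-01-01 to the extraction cutoff 2018-10-31, and the
#' 2010s therefore run only until 31 October 2018. Out-of-window dates are an
#' error rather than a silent extra bin.
#'
#' @param date A `Date` vector.
#' @param window Two dates bounding the analysis window.
#' @return Character vector of decade labels.
#' @examples
#' decade_of(as.Date(c("1969-12-31", "2018-10-31")))
#' @export
decade_of <- function(date,
                      window = as.Date(c("1960-01-01", "2018-10-31"))) {
  stopifnot(inherits(date, "Date"))
  out <- date < window[1] | date > window[2]
  if (any(out, na.rm = TRUE)) {
    stop(
      "date(s) outside the analysis window ",
      format(window[1]), " .. ", format(window[2]), ": ",
      paste(utils::head(format(date[which(out)]), 5), collapse = ", "),
      call. = FALSE
    )
  }
  year <- as.integer(format(date, "%Y"))
  paste0((year %/% 10) * 10, "s")
}

grouping_var <- function(level = c("country", "region", "subcountry")) {
  level <- match.arg(level)
  switch(level, region = "region", country = "country", subcountry = "unit")
}

#' Per-unit summaries with full filter accounting
#'
#' Summarizes a filter run (or a plain table of final records) per region,
#' country, or sub-country unit. With a `flam_filters` input the full
#' accounting columns are available — records entering after scoping,
#' duplicates, presence-only removals, final records — along with the
#' cumulative number of individuals and the year of the first (final) record.
#' Units with no records are omitted. Column sums are consistent across
#' levels by construction: region rows equal the sums of their member
#' countries.
#'
#' @param x A `flam_filters` object from [run_filters()], or a tibble of
#'   final records (then the pre-filter columns are reported as equal to the
#'   final counts).
#' @param scheme A `flam_scheme`.
#' @param level `"country"` (default), `"region"` or `"subcountry"`.
#' @return A tibble with one row per unit: `region`, `unit`, `n_record`,
#'   `n_duplicate`, `n_clean`, `n_qualitative`, `n_final`,
#'   `cum_individuals`, `first_record_year`.
#' @export
summarize_units <- function(x, scheme = default_region_scheme(),
                            level = c("country", "region", "subcountry")) {
  level <- match.arg(level)
  if (inherits(x, "flam_filters")) {
    ledger <- dplyr::filter(x$ledger, .data$status != "scoped_out")
  } else {
    validate_records(x)
    ledger <- dplyr::mutate(x, status = "final")
  }
  if (nrow(ledger) == 0) {
    return(tibble::tibble(
      region = character(), unit = character(),
      n_record = integer(), n_duplicate = integer(), n_clean = integer(),
      n_qualitative = integer(), n_final = integer(),
      cum_individuals = integer(), first_record_year = integer()
    ))
  }
  ledger <- assign_region(ledger, scheme)
  key <- grouping_var(level)
  ledger$unit_key <- ledger[[key]]
  out <- ledger |>
    dplyr::group_by(.data$region, .data$unit_key) |>
    dplyr::summarise(
      n_record = dplyr::n(),
      n_duplicate = sum(.data$status == "duplicate"),
      n_qualitative = sum(.data$status == "presence_only"),
      n_final = sum(.data$status == "final"),
      cum_individuals = sum(.data$count[.data$status == "final"]),
      first_record_year = if (any(.data$status == "final")) {
        min(as.integer(format(.data$date[.data$status == "final"], "%Y")))
      } else {
        NA_integer_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(n_clean = .data$n_record - .data$n_duplicate) |>
    dplyr::select(
      "region",
      unit = "unit_key", "n_record", "n_duplicate", "n_clean",
      "n_qualitative", "n_final", "cum_individuals", "first_record_year"
    ) |>
    dplyr::arrange(.data$region, .data$unit)
  if (level == "region") out$unit <- out$region
  out
}

#' Per-unit, per-decade record and individual totals
#'
#' Decade-resolved totals of final records and cumulative individuals.
#' Unit-by-decade cells with no records are absent from the output rather
#' than zero; per-unit sums over decades equal the unit totals of
#' [summarize_units()] on the same records.
#'
#' @param records Final (filtered) occurrence records.
#' @param scheme A `flam_scheme`.
#' @param level `"country"` (default), `"region"` or `"subcountry"`.
#' @return Tibble with `region`, `unit`, `decade`, `n_records`,
#'   `cum_individuals`.
#' @export
summarize_decades <- function(records, scheme = default_region_scheme(),
                              level = c("country", "region", "subcountry")) {
  level <- match.arg(level)
  validate_records(records)
  records <- assign_region(records, scheme)
  records$decade <- decade_of(records$date)
  key <- grouping_var(level)
  records$unit_key <- records[[key]]
  records |>
    dplyr::group_by(.data$region, .data$unit_key, .data$decade) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      cum_individuals = sum(.data$count),
      .groups = "drop"
    ) |>
    dplyr::select(
      "region",
      unit = "unit_key", "decade", "n_records", "cum_individuals"
    ) |>
    dplyr::arrange(.data$region, .data$unit, .data$decade)
}

#' Record days per unit: an observer-effort proxy
#'
#' The number of distinct calendar dates with at least one record in a unit.
#' A coarse index of birders' effort: more days in the field, more record
#' days, regardless of flock sizes. Always at most the unit's record count.
#'
#' @inheritParams summarize_decades
#' @return Tibble with `region`, `unit`, `n_record_days`.
#' @export
record_days <- function(records, scheme = default_region_scheme(),
                        level = c("country", "region", "subcountry")) {
  level <- match.arg(level)
  validate_records(records)
  records <- assign_region(records, scheme)
  key <- grouping_var(level)
  records$unit_key <- records[[key]]
  records |>
    dplyr::group_by(.data$region, .data$unit_key) |>
    dplyr::summarise(
      n_record_days = dplyr::n_distinct(.data$date),
      .groups = "drop"
    ) |>
    dplyr::select("region", unit = "unit_key", "n_record_days") |>
    dplyr::arrange(.data$region, .data$unit)
}

#' Individuals-per-record index per unit and decade
#'
#' The cumulative number of individuals divided by the number of records for
#' each unit-decade: a coarse correction for reporting effort, separating
#' growth in flock sizes from growth in the number of submitted checklists.
#' Defined only where a unit has at least one record in the decade (absent
#' rows, never zero); at least 1 whenever defined since every final record
#' counts at least one bird.
#'
#' @inheritParams summarize_decades
#' @return Tibble with `region`, `unit`, `decade`, `n_records`,
#'   `cum_individuals`, `individuals_per_record`.
#' @export
individuals_per_record_index <- function(records,
                                         scheme = default_region_scheme(),
                                         level = c("country", "region", "subcountry")) {
  level <- match.arg(level)
  if (any(is.na(records$count))) {
    stop(
      "presence-only records have no count; run the quantitative filter first",
      call. = FALSE
    )
  }
  summarize_decades(records, scheme, level) |>
    dplyr::mutate(
      individuals_per_record = .data$cum_individuals / .data$n_records
    )
}

#' Classify records against the recognized distribution
#'
#' Flags each record as inside (including on the boundary of) or outside the
#' recognized range polygon — the basis for spotting candidate range
#' extensions beyond the published distribution.
#'
#' @param records Occurrence-record tibble.
#' @param recognized_range Polygon or multipolygon; defaults to the coarse
#'   synthetic range shipped with the package.
#' @return The records with a logical `inside_range` column added.
#' @export
classify_against_range <- function(records,
                                   recognized_range = recognized_range_polygon()) {
  validate_records(records)
  dplyr::mutate(
    records,
    inside_range = point_in_polygon(
      records$longitude, records$latitude, recognized_range
    )
  )
}
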