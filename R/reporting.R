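table1_names <- c(
  Region = "region", Country = "unit", Record = "n_record",
  Duplicate = "n_duplicate", Record_clean = "n_clean",
  Record_qualitative = "n_qualitative", Record_final = "n_final",
  Number_of_individuals = "cum_individuals",
  Year_of_first_record = "first_record_year"
)

# Per-country accounting with region Total rows and a TOTAL ALL row,
# under the canonical exported column names.
accounting_with_totals <- function(units) {
  sum_cols <- c(
    "n_record", "n_duplicate", "n_clean", "n_qualitative", "n_final",
    "cum_individuals"
  )
  region_totals <- units |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(sum_cols), sum),
      .groups = "drop"
    ) |>
    dplyr::mutate(unit = "Total", first_record_year = NA_integer_)
  grand <- units |>
    dplyr::summarise(dplyr::across(dplyr::all_of(sum_cols), sum)) |>
    dplyr::mutate(
      region = "TOTAL ALL", unit = "TOTAL ALL",
      first_record_year = NA_integer_
    )
  stacked <- dplyr::bind_rows(
    purrr::map(split(units, units$region), function(block) {
      dplyr::bind_rows(
        block,
        region_totals[region_totals$region == block$region[1], ]
      )
    })
  )
  out <- dplyr::bind_rows(stacked, grand)
  out <- out[unname(table1_names)]
  names(out) <- names(table1_names)
  out
}

# Breeding table rendered with presentation rounding and the critical flag.
breeding_presentation <- function(tab, reference_unit) {
  flag_critical(tab, reference_unit) |>
    dplyr::transmute(
      Region = .data$region,
      Country = .data$unit,
      Number_of_individuals = .data$breeding_individuals,
      Percentage_breeding = round_half_up(.data$pct_breeding, 4),
      Number_of_years = .data$n_years,
      Average_per_year = round_half_up(.data$avg_per_year, 1),
      SD = round_half_up(.data$sd_per_year, 1),
      Min = .data$min_year_total,
      Max = .data$max_year_total,
      Critical = .data$is_critical
    )
}

write_manifest <- function(path, entries) {
  lines <- paste0(names(entries), ": ", unname(unlist(entries)))
  write_atomically(function(tmp) writeLines(lines, tmp), path)
}

#' Simulate a dataset to a TSV file
#'
#' Generates a synthetic occurrence dataset and writes it in the eBird-like
#' TSV dialect, together with a plain-text manifest recording the
#' configuration so the run can be reproduced byte-for-byte.
#'
#' @param config A `flam_config` object, or the path of a YAML configuration
#'   file (see [read_synthetic_config()]).
#' @param out Output TSV path; the manifest is written next to it as
#'   `<out>.manifest.txt`.
#' @return Invisibly, a list with the records and the two output paths.
#' @export
simulate_dataset <- function(config = synthetic_config(), out) {
  if (is.character(config)) config <- read_synthetic_config(config)
  stopifnot(inherits(config, "flam_config"))
  records <- generate_occurrences(config)
  write_records(records, out)
  manifest <- paste0(out, ".manifest.txt")
  write_manifest(manifest, list(
    tool = paste0("flamingr ", as.character(utils::packageVersion("flamingr"))),
    command = "simulate",
    seed = config$seed,
    colonies = paste(config$colonies$name, collapse = "; "),
    effort = paste(names(config$effort), config$effort, sep = "=", collapse = " "),
    duplicate_prob = config$duplicate_prob,
    presence_only_prob = config$presence_only_prob,
    out_of_scope_count = config$out_of_scope_count,
    date_window = paste(format(config$date_window), collapse = " .. "),
    n_records = nrow(records),
    output = out
  ))
  invisible(list(records = records, tsv = out, manifest = manifest))
}

#' Run the end-to-end analysis and export all tables
#'
#' Ties the stages together: record cleaning with accounting, per-country
#' and per-decade summaries, breeding-season importance with the critical
#' flag, effort indices, and range classification. Writes, into `out_dir`:
#' \describe{
#'   \item{Table1.csv}{per-country accounting with region totals and a grand
#'     total, columns `Record`, `Duplicate`, `Record_clean`,
#'     `Record_qualitative`, `Record_final`, `Number_of_individuals`,}
#'   \item{S1_decades.csv}{per-country, per-decade records and individuals,}
#'   \item{Table2.csv}{breeding-importance table (presentation rounding:
#'     percentage 4 decimals, average/SD 1 decimal) with a `Critical`
#'     boolean column,}
#'   \item{S2_yearly.csv}{unit-by-year breeding-season individuals,}
#'   \item{effort.csv}{individuals-per-record index per unit and decade plus
#'     per-unit record days,}
#'   \item{points.geojson}{final records flagged inside/outside the
#'     recognized range,}
#'   \item{manifest.txt}{inputs, parameters and per-stage accounting.}
#' }
#' All files are written atomically; re-running on identical inputs yields
#' identical bytes.
#'
#' @param records Occurrence-record tibble, or the path of a TSV readable by
#'   [read_records()].
#' @param out_dir Output directory, created if needed.
#' @param scheme A `flam_scheme`.
#' @param scope Scope polygon for the geographic filter.
#' @param window Breeding-assessment years, default `2010:2018`.
#' @param reference_unit Reference unit for the critical threshold.
#' @return Invisibly, a list with the filter result, the summary tables and
#'   the output paths.
#' @export
run_analysis <- function(records, out_dir,
                         scheme = default_region_scheme(),
                         scope = americas_polygon(),
                         window = 2010:2018,
                         reference_unit = "Ecuador") {
  input_label <- "<in-memory records>"
  if (is.character(records)) {
    input_label <- records
    records <- read_records(records)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  filters <- run_filters(records, scope = scope)
  units <- summarize_units(filters, scheme, level = "country")
  table1 <- accounting_with_totals(units)
  decades <- summarize_decades(filters$records, scheme, level = "country")
  breeding <- breeding_table(filters$records, scheme, window = window)
  table2 <- breeding_presentation(breeding, reference_unit)
  yearly <- yearly_breeding_series(filters$records, scheme, window) |>
    tidyr::pivot_wider(
      names_from = "year", values_from = "cum_individuals", names_sort = TRUE
    )
  effort <- individuals_per_record_index(
    filters$records, scheme,
    level = "country"
  ) |>
    dplyr::left_join(
      record_days(filters$records, scheme, level = "country"),
      by = c("region", "unit")
    )
  classified <- classify_against_range(filters$records, scheme$recognized_range)

  paths <- list(
    table1 = file.path(out_dir, "Table1.csv"),
    decades = file.path(out_dir, "S1_decades.csv"),
    table2 = file.path(out_dir, "Table2.csv"),
    yearly = file.path(out_dir, "S2_yearly.csv"),
    effort = file.path(out_dir, "effort.csv"),
    points = file.path(out_dir, "points.geojson"),
    manifest = file.path(out_dir, "manifest.txt")
  )
  csv <- function(df, path) {
    write_atomically(function(tmp) readr::write_csv(df, tmp, progress = FALSE), path)
  }
  csv(table1, paths$table1)
  csv(
    stats::setNames(
      decades,
      c("Region", "Country", "Decade", "Records", "Number_of_individuals")
    ),
    paths$decades
  )
  csv(table2, paths$table2)
  csv(yearly, paths$yearly)
  csv(
    stats::setNames(effort, c(
      "Region", "Country", "Decade", "Records", "Number_of_individuals",
      "Individuals_per_record", "Record_days"
    )),
    paths$effort
  )
  write_points_geojson(classified, paths$points)

  a <- filters$accounting
  write_manifest(paths$manifest, list(
    tool = paste0("flamingr ", as.character(utils::packageVersion("flamingr"))),
    command = "analyze",
    input = input_label,
    scheme_countries = length(scheme$country_to_region),
    window = paste(range(window), collapse = ":"),
    reference_unit = reference_unit,
    stage_scope = sprintf(
      "in=%d removed=%d out=%d",
      a$n_record + a$n_scoped_out, a$n_scoped_out, a$n_record
    ),
    stage_deduplicate = sprintf(
      "in=%d removed=%d out=%d", a$n_record, a$n_duplicate, a$n_clean
    ),
    stage_quantitative = sprintf(
      "in=%d removed=%d out=%d", a$n_clean, a$n_qualitative, a$n_final
    ),
    cum_individuals = a$cum_individuals,
    outputs = paste(basename(unlist(paths)), collapse = " ")
  ))

  invisible(list(
    filters = filters, table1 = table1, decades = decades,
    breeding = breeding, table2 = table2, yearly = yearly, effort = effort,
    classified = classified, paths = paths
  ))
}

#' Compare produced output tables against expected fixtures
#'
#' Reads every CSV present in `expected_dir`, compares it cell-by-cell
#' against the file of the same name in `out_dir`, and reports one diff line
#' per mismatching cell. Intended as the end of an analysis run: a
#' regression gate against a frozen set of expected tables.
#'
#' @param out_dir Directory of produced outputs.
#' @param expected_dir Directory of expected CSV fixtures.
#' @return A `flam_check` object with elements `pass` (logical) and `diffs`
#'   (tibble with `file`, `row`, `column`, `expected`, `actual`).
#' @export
check_outputs <- function(out_dir, expected_dir) {
  files <- list.files(expected_dir, pattern = "\\.csv$")
  if (length(files) == 0) {
    stop("no CSV fixtures found in ", expected_dir, call. = FALSE)
  }
  read_chr <- function(path) {
    readr::read_csv(
      path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  diffs <- purrr::map_dfr(files, function(f) {
    produced_path <- file.path(out_dir, f)
    if (!file.exists(produced_path)) {
      return(tibble::tibble(
        file = f, row = NA_integer_, column = NA_character_,
        expected = "<file>", actual = "<missing>"
      ))
    }
    expected <- read_chr(file.path(expected_dir, f))
    actual <- read_chr(produced_path)
    if (!identical(dim(expected), dim(actual)) ||
      !identical(names(expected), names(actual))) {
      return(tibble::tibble(
        file = f, row = NA_integer_, column = NA_character_,
        expected = paste(dim(expected), collapse = "x"),
        actual = paste(dim(actual), collapse = "x")
      ))
    }
    purrr::map_dfr(names(expected), function(col) {
      mism <- which(
        !(expected[[col]] == actual[[col]] |
          (is.na(expected[[col]]) & is.na(actual[[col]])))
      )
      tibble::tibble(
        file = f, row = mism, column = col,
        expected = expected[[col]][mism], actual = actual[[col]][mism]
      )
    })
  })
  structure(list(pass = nrow(diffs) == 0, diffs = diffs), class = "flam_check")
}

#' @export
print.flam_check <- function(x, ...) {
  if (x$pass) {
    cat("PASS: all compared cells match\n")
  } else {
    cat("FAIL:", nrow(x$diffs), "mismatching cell(s)\n")
    apply(x$diffs, 1, function(d) {
      cat(sprintf(
        "  %s [row %s, %s]: expected %s, got %s\n",
        d[["file"]], d[["row"]], d[["column"]], d[["expected"]], d[["actual"]]
      ))
    })
  }
  invisible(x)
}
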