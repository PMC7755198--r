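#' Breeding vs non-breeding season of a date
#'
#' American Flamingos breed mostly from April through August; September
#' through March is the non-breeding season. Classification uses the month
#' only.
#'
#' @param date A `Date` vector.
#' @return Character vector, `"breeding"` or `"nonbreeding"`.
#' @examples
#' season_of(as.Date(c("2015-04-01", "2015-09-01")))
#' @export
season_of <- function(date) {
  stopifnot(inherits(date, "Date"))
  month <- as.integer(format(date, "%m"))
  ifelse(month >= 4 & month <= 8, "breeding", "nonbreeding")
}

#' Per-unit yearly breeding-season individual totals
#'
#' The cumulative number of individuals per calendar year, counting only
#' breeding-season (April-August) records inside the window. Years with no
#' breeding-season records are absent, not zero. Feeds the per-year
#' average/SD/min/max statistics of [breeding_table()].
#'
#' @param records Final (filtered) occurrence records.
#' @param scheme A `flam_scheme`; sub-country units are used where defined.
#' @param window Integer vector of calendar years, default `2010:2018`
#'   (nine breeding seasons).
#' @return Tibble with `region`, `unit`, `year`, `cum_individuals`.
#' @export
yearly_breeding_series <- function(records, scheme = default_region_scheme(),
                                   window = 2010:2018) {
  validate_records(records)
  stopifnot(length(window) >= 1)
  records <- assign_region(records, scheme)
  records$year <- as.integer(format(records$date, "%Y"))
  records |>
    dplyr::filter(
      season_of(.data$date) == "breeding",
      .data$year %in% window,
      !is.na(.data$count)
    ) |>
    dplyr::group_by(.data$region, .data$unit, .data$year) |>
    dplyr::summarise(cum_individuals = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$region, .data$unit, .data$year)
}

#' Breeding-season importance table
#'
#' Scores each geographic unit's importance as a potential breeding site:
#' the cumulative number of individuals reported during the breeding seasons
#' (April-August) of the window years, as a percentage of the total over all
#' units with at least one breeding-season record in the window. Only such
#' units enter the table — and the denominator — so adding a unit observed
#' exclusively outside the breeding season changes nothing. Per-year summary
#' statistics accompany the percentage: the average is
#' `breeding_individuals / n_years`; the sample standard deviation of the
#' yearly totals is reported only for units with at least three years of
#' data, the min/max only with at least two (`NA` otherwise).
#'
#' All columns are exact; apply [round_half_up()] (4 decimals for the
#' percentage, 1 for average and SD) only when presenting.
#'
#' @inheritParams yearly_breeding_series
#' @return A `flam_breeding` tibble with columns `region`, `unit`,
#'   `breeding_individuals`, `pct_breeding`, `n_years`, `avg_per_year`,
#'   `sd_per_year`, `min_year_total`, `max_year_total`; the window and the
#'   denominator are carried as attributes (see [glance()]).
#' @examples
#' recs <- generate_occurrences(synthetic_config(seed = 1))
#' final <- run_filters(recs)$records
#' breeding_table(final)
#' @export
breeding_table <- function(records, scheme = default_region_scheme(),
                           window = 2010:2018) {
  series <- yearly_breeding_series(records, scheme, window)
  if (nrow(series) == 0) {
    stop(
      "no breeding-season records in the window ",
      min(window), "-", max(window),
      call. = FALSE
    )
  }
  tab <- series |>
    dplyr::group_by(.data$region, .data$unit) |>
    dplyr::summarise(
      breeding_individuals = sum(.data$cum_individuals),
      n_years = dplyr::n_distinct(.data$year),
      sd_per_year = if (dplyr::n() >= 3) {
        stats::sd(.data$cum_individuals)
      } else {
        NA_real_
      },
      min_year_total = if (dplyr::n() >= 2) min(.data$cum_individuals) else NA_real_,
      max_year_total = if (dplyr::n() >= 2) max(.data$cum_individuals) else NA_real_,
      .groups = "drop"
    )
  denominator <- sum(tab$breeding_individuals)
  tab <- tab |>
    dplyr::mutate(
      pct_breeding = 100 * .data$breeding_individuals / denominator,
      avg_per_year = .data$breeding_individuals / .data$n_years
    ) |>
    dplyr::select(
      "region", "unit", "breeding_individuals", "pct_breeding", "n_years",
      "avg_per_year", "sd_per_year", "min_year_total", "max_year_total"
    ) |>
    dplyr::arrange(.data$region, .data$unit)
  structure(
    tab,
    class = c("flam_breeding", class(tab)),
    window = window,
    denominator = denominator
  )
}

#' One-row summary of a breeding-importance table
#'
#' @param x A `flam_breeding` table.
#' @param ... Unused.
#' @return Tibble with the window bounds, the number of units and the
#'   denominator (total breeding-season individuals over included units).
#' @method glance flam_breeding
#' @export
glance.flam_breeding <- function(x, ...) {
  window <- attr(x, "window")
  tibble::tibble(
    window_start = min(window),
    window_end = max(window),
    n_units = nrow(x),
    total_breeding_individuals = attr(x, "denominator")
  )
}

#' Critical potential breeding units under a reference threshold
#'
#' The reference site sets the bar: every unit whose breeding-importance
#' percentage is at least the reference unit's percentage is flagged
#' critical. The comparison is inclusive, so the reference site — a small but
#' confirmed, isolated breeding population — always classifies itself.
#'
#' @param table A `flam_breeding` table from [breeding_table()].
#' @param reference_unit Unit name supplying the threshold, default
#'   `"Ecuador"` (the Galapagos population).
#' @return Character vector of critical unit names, sorted alphabetically.
#' @examples
#' recs <- generate_occurrences(synthetic_config(seed = 1))
#' tab <- breeding_table(run_filters(recs)$records)
#' classify_critical(tab, "Ecuador")
#' @export
classify_critical <- function(table, reference_unit = "Ecuador") {
  stopifnot(inherits(table, "flam_breeding"))
  if (!reference_unit %in% table$unit) {
    stop(
      "reference unit '", reference_unit, "' is not in the table",
      call. = FALSE
    )
  }
  threshold <- table$pct_breeding[table$unit == reference_unit]
  sort(table$unit[table$pct_breeding >= threshold])
}

#' Add the critical flag to a breeding table
#'
#' @inheritParams classify_critical
#' @return The table with a logical `is_critical` column.
#' @export
flag_critical <- function(table, reference_unit = "Ecuador") {
  critical <- classify_critical(table, reference_unit)
  dplyr::mutate(table, is_critical = .data$unit %in% critical)
}

#' Bar chart of breeding-importance percentages
#'
#' @param object A `flam_breeding` table.
#' @param reference_unit Optional unit whose percentage is drawn as the
#'   critical threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flam_breeding
#' @export
autoplot.flam_breeding <- function(object, reference_unit = NULL, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$pct_breeding)
  df$unit <- factor(df$unit, levels = df$unit)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pct_breeding, y = .data$unit)) +
    ggplot2::geom_col(fill = "#e0639c") +
    ggplot2::labs(
      x = "% of breeding-season individuals", y = NULL,
      title = "Breeding-season importance by unit"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(reference_unit) && reference_unit %in% df$unit) {
    thr <- df$pct_breeding[df$unit == reference_unit]
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed")
  }
  p
}
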