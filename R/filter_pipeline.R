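#' @keywords internal
# Deduplication key: eBird locality when present, else coordinates rounded
# to `coord_digits` decimals (~11 m at 4 digits).
location_key <- function(records, coord_digits = 4) {
  ifelse(
    records$locality_id != "",
    paste0("loc:", records$locality_id),
    sprintf(
      "xy:%.*f,%.*f",
      coord_digits, records$latitude, coord_digits, records$longitude
    )
  )
}

#' Geographic scope filter
#'
#' Keeps exactly the records whose point lies inside or on the scope polygon;
#' out-of-range records (e.g. escaped or captive birds reported on another
#' continent) are removed before any other cleaning.
#'
#' @param records Occurrence-record tibble.
#' @param scope Scope polygon (matrix or list of matrices); defaults to
#'   [americas_polygon()].
#' @return The kept records; the removed rows are attached as an attribute
#'   and retrievable with [removed_records()].
#' @seealso [run_filters()] for the full pipeline with accounting.
#' @export
filter_scope <- function(records, scope = americas_polygon()) {
  validate_records(records)
  inside <- point_in_polygon(records$longitude, records$latitude, scope)
  kept <- records[inside, ]
  attr(kept, "flam_removed") <- records[!inside, ]
  kept
}

#' One-record-per-location-per-day deduplication
#'
#' Multiple checklists submitted for the same location on the same day are
#' redundant sightings of the same birds. Within each (location key, date)
#' group one representative survives: the record with the largest numeric
#' count (presence-only ranks below any numeric count), remaining ties broken
#' by lexicographically smallest record id, so output is deterministic.
#' Idempotent: deduplicating already-deduplicated records removes nothing.
#'
#' @inheritParams filter_scope
#' @param coord_digits Decimal places for the coordinate fallback key used
#'   when a record has no locality id.
#' @return The kept records (one per group, input order preserved); removed
#'   rows retrievable with [removed_records()].
#' @export
dedupe_records <- function(records, coord_digits = 4) {
  validate_records(records)
  if (nrow(records) == 0) {
    attr(records, "flam_removed") <- records
    return(records)
  }
  key <- paste(location_key(records, coord_digits), records$date)
  # representative rank: highest count first, X (NA) last, then smallest id
  ord <- order(
    key,
    -ifelse(is.na(records$count), -1, records$count),
    records$record_id
  )
  is_rep_sorted <- !duplicated(key[ord])
  keep <- logical(nrow(records))
  keep[ord] <- is_rep_sorted
  kept <- records[keep, ]
  attr(kept, "flam_removed") <- records[!keep, ]
  kept
}

#' Quantitative-count filter
#'
#' Keeps records providing an actual number of individuals, removing
#' presence-only (`"X"`) records. Run after deduplication: a group holding
#' both a numeric and a presence-only checklist is represented by the numeric
#' one, so the group contributes nothing to the presence-only removal count.
#'
#' @inheritParams filter_scope
#' @return The kept records; removed rows retrievable with
#'   [removed_records()].
#' @export
filter_quantitative <- function(records) {
  validate_records(records)
  keep <- !is.na(records$count)
  kept <- records[keep, ]
  attr(kept, "flam_removed") <- records[!keep, ]
  kept
}

#' Rows removed by the last filtering step
#'
#' @param records A tibble returned by [filter_scope()], [dedupe_records()]
#'   or [filter_quantitative()].
#' @return Tibble of removed rows (zero rows if nothing was removed).
#' @export
removed_records <- function(records) {
  removed <- attr(records, "flam_removed")
  if (is.null(removed)) records[0, ] else removed
}

#' Run the full record-cleaning pipeline with accounting
#'
#' Applies, in order: geographic scoping, one-record-per-location-per-day
#' deduplication, and the quantitative-count filter. Every input record is
#' assigned exactly one fate — `scoped_out`, `duplicate`, `presence_only` or
#' `final` — so the accounting identities hold by construction:
#' `Record_clean = Record - Duplicate` and
#' `Record_final = Record_clean - Record_qualitative`.
#'
#' @inheritParams dedupe_records
#' @param scope Scope polygon; defaults to [americas_polygon()].
#' @return A `flam_filters` object: a list with
#'   \describe{
#'     \item{records}{the final (clean, quantitative) records,}
#'     \item{ledger}{every input record with a `status` column recording its
#'       fate — the basis for per-country accounting,}
#'     \item{accounting}{a one-row tibble with `n_record` (records entering
#'       after scoping), `n_duplicate`, `n_clean`, `n_qualitative`, `n_final`
#'       and `cum_individuals` (sum of counts over final records; may recount
#'       the same birds seen on different days).}
#'   }
#'   Use [tidy()] for the per-stage flow and [glance()] for the accounting
#'   row.
#' @examples
#' recs <- generate_occurrences(synthetic_config(seed = 1))
#' fit <- run_filters(recs)
#' glance(fit)
#' @export
run_filters <- function(records, scope = americas_polygon(), coord_digits = 4) {
  validate_records(records)
  scoped <- filter_scope(records, scope)
  clean <- dedupe_records(scoped, coord_digits)
  final <- filter_quantitative(clean)

  status <- stats::setNames(rep("final", nrow(records)), records$record_id)
  status[removed_records(scoped)$record_id] <- "scoped_out"
  status[removed_records(clean)$record_id] <- "duplicate"
  status[removed_records(final)$record_id] <- "presence_only"
  ledger <- dplyr::mutate(records, status = unname(status[records$record_id]))

  accounting <- tibble::tibble(
    n_scoped_out = sum(ledger$status == "scoped_out"),
    n_record = nrow(scoped),
    n_duplicate = sum(ledger$status == "duplicate"),
    n_clean = nrow(clean),
    n_qualitative = sum(ledger$status == "presence_only"),
    n_final = nrow(final),
    cum_individuals = sum(final$count)
  )
  stopifnot(
    accounting$n_clean == accounting$n_record - accounting$n_duplicate,
    accounting$n_final == accounting$n_clean - accounting$n_qualitative
  )

  structure(
    list(
      records = tibble::as_tibble(final),
      ledger = ledger,
      accounting = accounting,
      scope = scope,
      coord_digits = coord_digits
    ),
    class = "flam_filters"
  )
}

#' @export
print.flam_filters <- function(x, ...) {
  a <- x$accounting
  cat("<flam_filters> record-cleaning accounting\n")
  cat(sprintf("  input records:     %d\n", a$n_record + a$n_scoped_out))
  cat(sprintf("  out of scope:      %d\n", a$n_scoped_out))
  cat(sprintf("  in scope (Record): %d\n", a$n_record))
  cat(sprintf("  duplicates:        %d\n", a$n_duplicate))
  cat(sprintf("  presence-only:     %d\n", a$n_qualitative))
  cat(sprintf("  final records:     %d\n", a$n_final))
  cat(sprintf("  cum. individuals:  %s\n", format(a$cum_individuals, big.mark = ",")))
  invisible(x)
}

#' Tidy the per-stage record flow of a filter run
#'
#' @param x A `flam_filters` object from [run_filters()].
#' @param ... Unused.
#' @return A tibble with one row per stage: records entering, removed and
#'   surviving.
#' @method tidy flam_filters
#' @export
tidy.flam_filters <- function(x, ...) {
  a <- x$accounting
  tibble::tibble(
    stage = c("scope", "deduplicate", "quantitative"),
    n_in = c(a$n_record + a$n_scoped_out, a$n_record, a$n_clean),
    n_removed = c(a$n_scoped_out, a$n_duplicate, a$n_qualitative),
    n_out = c(a$n_record, a$n_clean, a$n_final)
  )
}

#' One-row accounting summary of a filter run
#'
#' @inheritParams tidy.flam_filters
#' @return The accounting tibble (`n_record`, `n_duplicate`, `n_clean`,
#'   `n_qualitative`, `n_final`, `cum_individuals`).
#' @method glance flam_filters
#' @export
glance.flam_filters <- function(x, ...) {
  x$accounting
}

#' Funnel plot of a filter run
#'
#' @param object A `flam_filters` object.
#' @param ... Unused.
#' @return A ggplot bar chart of record counts surviving each stage.
#' @method autoplot flam_filters
#' @export
autoplot.flam_filters <- function(object, ...) {
  a <- object$accounting
  df <- tibble::tibble(
    stage = factor(
      c("input", "in scope", "deduplicated", "final"),
      levels = c("input", "in scope", "deduplicated", "final")
    ),
    n = c(a$n_record + a$n_scoped_out, a$n_record, a$n_clean, a$n_final)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "#e0639c") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = NULL, y = "records",
      title = "Record-cleaning funnel"
    ) +
    ggplot2::theme_minimal()
}
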