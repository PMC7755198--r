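#' Published per-country reference tables
#'
#' Two small reference tables from the published continental assessment of
#' American Flamingo eBird records, shipped as plain CSV under `extdata`.
#'
#' `published_accounting()` holds the per-country record accounting for
#' 1960 to October 2018: records entering after geographic scoping
#' (`n_record`), duplicates removed (`n_duplicate`), presence-only records
#' removed (`n_qualitative`), final records (`n_final`), the cumulative
#' number of individuals over final records, and the year of the first
#' record. Region and grand totals are always recomputed as column sums
#' rather than stored (two printed total cells in the source table are
#' internally inconsistent with their own rows by a few units).
#'
#' `published_breeding()` holds the per-unit breeding-season totals for the
#' 2010-2018 window: cumulative individuals over the nine April-August
#' seasons and the number of years with data, at sub-country resolution for
#' Mexico and the USA. Unit names use the package's canonical spellings. The
#' `country`/`subnational` columns give a representative placement of each
#' unit so the rows can be replayed through the pipeline with
#' [generate_matching_breeding()].
#'
#' @return A tibble.
#' @examples
#' published_accounting()
#' sum(published_accounting()$n_final) # 9283
#' @export
published_accounting <- function() {
  readr::read_csv(
    system.file(
      "extdata", "published_accounting_1960_2018.csv",
      package = "flamingr"
    ),
    col_types = "cciiiiii", progress = FALSE
  )
}

#' @rdname published_accounting
#' @export
published_breeding <- function() {
  out <- readr::read_csv(
    system.file(
      "extdata", "published_breeding_2010_2018.csv",
      package = "flamingr"
    ),
    col_types = "ccccii", progress = FALSE
  )
  out$subnational[is.na(out$subnational)] <- ""
  out
}
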