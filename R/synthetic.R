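#' Default synthetic colonies
#'
#' Six colonies spanning the four regions, loosely modelled on the species'
#' well-known sites: a small isolated Galapagos-like colony (the reference
#' site), a very large Venezuelan colony contributing roughly 46% of expected
#' breeding-season individuals, and mid-sized colonies on the Yucatan
#' Peninsula, in Cuba, the Bahamas and Bonaire. `mean_count` is the expected
#' flock size per checklist outside the breeding season; during April-August
#' the mean is multiplied by `breeding_multiplier`. `dispersion` is the
#' negative-binomial size parameter (smaller = heavier-tailed flock sizes).
#'
#' @return A tibble, one row per colony.
#' @export
default_colonies <- function() {
  tibble::tribble(
    ~name, ~country, ~subnational, ~latitude, ~longitude,
    ~mean_count, ~dispersion, ~breeding_multiplier,
    "Galapagos", "Ecuador", "Gal\u00e1pagos", -0.95, -90.97, 18, 2.0, 1.5,
    "Los Olivitos", "Venezuela", "Zulia", 10.90, -71.50, 2600, 0.8, 2.0,
    "Ria Lagartos", "Mexico", "Yucat\u00e1n", 21.57, -88.16, 1500, 0.8, 2.0,
    "Rio Maximo", "Cuba", "Camag\u00fcey", 21.80, -77.90, 800, 0.8, 2.0,
    "Great Inagua", "Bahamas", "", 21.00, -73.30, 400, 1.0, 1.5,
    "Goto Meer", "Bonaire", "", 12.22, -68.37, 500, 1.0, 1.8
  )
}

#' Configuration for the synthetic occurrence generator
#'
#' Bundles everything [generate_occurrences()] needs: the colonies, the
#' per-decade observer effort (expected checklists per colony, growing
#' decade over decade with a strong 2010s surge), the probability that a
#' checklist is shadowed by a same-location same-day second checklist
#' (a duplicate), the probability that a count is reported as the
#' presence-only token `"X"`, the number of out-of-scope (European) records,
#' the date window, and the seed. Identical config + seed always yields an
#' identical dataset.
#'
#' @param colonies Colony tibble, see [default_colonies()].
#' @param effort Named numeric vector of expected checklists per colony per
#'   decade, names `"1960s"` .. `"2010s"`.
#' @param duplicate_prob Probability in `[0, 1]` of an extra same-key
#'   checklist per base checklist.
#' @param presence_only_prob Probability in `[0, 1]` that a record reports
#'   `"X"` instead of a number.
#' @param out_of_scope_count Number of records placed outside the Americas
#'   scope polygon (emulating captive-bird reports from Europe).
#' @param date_window Two dates bounding record dates.
#' @param seed Integer seed for the single pseudo-random stream.
#' @return A `flam_config` object (a validated list).
#' @export
synthetic_config <- function(colonies = default_colonies(),
                             effort = c(
                               "1960s" = 2, "1970s" = 4, "1980s" = 8,
                               "1990s" = 15, "2000s" = 30, "2010s" = 120
                             ),
                             duplicate_prob = 0.25,
                             presence_only_prob = 0.12,
                             out_of_scope_count = 18,
                             date_window = as.Date(c("1960-01-01", "2018-10-31")),
                             seed = 42) {
  colonies <- tibble::as_tibble(colonies)
  needed <- c(
    "name", "country", "subnational", "latitude", "longitude",
    "mean_count", "dispersion", "breeding_multiplier"
  )
  stopifnot(all(needed %in% names(colonies)), nrow(colonies) >= 1)
  if (duplicate_prob < 0 || duplicate_prob > 1 ||
    presence_only_prob < 0 || presence_only_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(colonies$mean_count < 1) || any(colonies$dispersion <= 0) ||
    any(colonies$breeding_multiplier < 1)) {
    stop(
      "colonies need mean_count >= 1, dispersion > 0, breeding_multiplier >= 1",
      call. = FALSE
    )
  }
  stopifnot(
    is.numeric(effort), !is.null(names(effort)), all(effort >= 0),
    length(date_window) == 2, inherits(date_window, "Date"),
    out_of_scope_count >= 0
  )
  structure(
    list(
      colonies = colonies, effort = effort,
      duplicate_prob = duplicate_prob,
      presence_only_prob = presence_only_prob,
      out_of_scope_count = as.integer(out_of_scope_count),
      date_window = date_window, seed = as.integer(seed)
    ),
    class = "flam_config"
  )
}

#' @export
print.flam_config <- function(x, ...) {
  cat("<flam_config>\n")
  cat("  colonies:", paste(x$colonies$name, collapse = ", "), "\n")
  cat("  effort/decade:", paste(names(x$effort), x$effort, sep = "=", collapse = " "), "\n")
  cat(sprintf(
    "  duplicate_prob=%.2f presence_only_prob=%.2f out_of_scope=%d seed=%d\n",
    x$duplicate_prob, x$presence_only_prob, x$out_of_scope_count, x$seed
  ))
  invisible(x)
}

#' Read / write a generator configuration (YAML)
#'
#' The YAML schema mirrors the arguments of [synthetic_config()]: scalar keys
#' `duplicate_prob`, `presence_only_prob`, `out_of_scope_count`, `seed`,
#' a `date_window` list of two ISO dates, an `effort` mapping of decade
#' labels to expected checklists, and a `colonies` list whose entries carry
#' the [default_colonies()] fields.
#'
#' @param path Path of a YAML configuration file.
#' @return `read_synthetic_config()`: a `flam_config`;
#'   `write_synthetic_config()`: the path, invisibly.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- synthetic_config()
  colonies <- if (is.null(y$colonies)) {
    defaults$colonies
  } else {
    dplyr::bind_rows(lapply(y$colonies, tibble::as_tibble))
  }
  synthetic_config(
    colonies = colonies,
    effort = if (is.null(y$effort)) defaults$effort else unlist(y$effort),
    duplicate_prob = y$duplicate_prob %||% defaults$duplicate_prob,
    presence_only_prob = y$presence_only_prob %||% defaults$presence_only_prob,
    out_of_scope_count = y$out_of_scope_count %||% defaults$out_of_scope_count,
    date_window = if (is.null(y$date_window)) {
      defaults$date_window
    } else {
      as.Date(unlist(y$date_window))
    },
    seed = y$seed %||% defaults$seed
  )
}

#' @rdname read_synthetic_config
#' @param config A `flam_config` object.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "flam_config"))
  y <- list(
    colonies = lapply(
      seq_len(nrow(config$colonies)),
      function(i) as.list(config$colonies[i, ])
    ),
    effort = as.list(config$effort),
    duplicate_prob = config$duplicate_prob,
    presence_only_prob = config$presence_only_prob,
    out_of_scope_count = config$out_of_scope_count,
    date_window = format(config$date_window, "%Y-%m-%d"),
    seed = config$seed
  )
  write_atomically(function(tmp) yaml::write_yaml(y, tmp), path)
}

# Snap coordinates to the 6-decimal precision of the TSV dialect so that
# generated datasets survive a write/read cycle bit-for-bit.
snap6 <- function(x) as.numeric(sprintf("%.6f", x))

decade_days <- function(decade_label, window) {
  start <- as.integer(sub("s$", "", decade_label))
  lo <- max(as.Date(sprintf("%d-01-01", start)), window[1])
  hi <- min(as.Date(sprintf("%d-12-31", start + 9)), window[2])
  if (lo > hi) return(as.Date(character()))
  seq(lo, hi, by = "day")
}

#' Generate a synthetic eBird-like occurrence dataset
#'
#' Emulates the structural features of a citizen-science extract that the
#' cleaning pipeline must handle: spatially clustered colonies with
#' heavy-tailed (negative-binomial) flock sizes, April-August breeding
#' aggregation via the colony's `breeding_multiplier`, same-location
#' same-day duplicate checklists, presence-only (`"X"`) counts,
#' decade-over-decade growth in observer effort, and a few out-of-scope
#' records placed in Europe. Base checklists within a colony always occupy
#' distinct (locality, date) keys, so the only duplicates are the injected
#' ones; an injected duplicate reports either a strictly smaller count than
#' its base checklist or `"X"`, and its record id sorts after the base id, so
#' deduplication always retains the base checklist.
#'
#' @param config A `flam_config`, see [synthetic_config()].
#' @return An occurrence-record tibble (see [read_records()]) ordered by
#'   date; deterministic given the config's seed, and the caller's RNG state
#'   is left untouched.
#' @examples
#' recs <- generate_occurrences(synthetic_config(seed = 1))
#' dplyr::count(recs, country)
#' @export
generate_occurrences <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "flam_config"))
  with_seed(config$seed, generate_occurrences_impl(config))
}

generate_occurrences_impl <- function(config) {
  n_localities <- 3L
  pieces <- list()
  serial <- 0L

  for (ci in seq_len(nrow(config$colonies))) {
    colony <- config$colonies[ci, ]
    for (decade in names(config$effort)) {
      days <- decade_days(decade, config$date_window)
      if (length(days) == 0 || config$effort[[decade]] == 0) next
      n <- stats::rpois(1, config$effort[[decade]])
      n <- min(n, n_localities * length(days))
      if (n == 0) next
      # distinct (locality, date) combos guarantee unique base keys
      combo <- sample.int(n_localities * length(days), n)
      loc_idx <- (combo - 1L) %/% length(days) + 1L
      date <- days[(combo - 1L) %% length(days) + 1L]
      month <- as.integer(format(date, "%m"))
      mu <- colony$mean_count *
        ifelse(month >= 4 & month <= 8, colony$breeding_multiplier, 1)
      count <- pmax(1, stats::rnbinom(n, size = colony$dispersion, mu = mu))
      count[stats::runif(n) < config$presence_only_prob] <- NA

      ids <- serial + seq_len(n)
      serial <- serial + n
      base <- tibble::tibble(
        record_id = sprintf("S%07da", ids),
        country = colony$country,
        subnational = colony$subnational,
        locality_id = sprintf("C%02d-L%d", ci, loc_idx),
        latitude = snap6(colony$latitude + 0.01 * loc_idx),
        longitude = snap6(colony$longitude + 0.01 * loc_idx),
        date = date,
        count = as.integer(count)
      )
      pieces[[length(pieces) + 1]] <- base

      dup_sel <- which(stats::runif(n) < config$duplicate_prob)
      if (length(dup_sel) > 0) {
        dup <- base[dup_sel, ]
        dup$record_id <- sprintf("S%07dz", ids[dup_sel])
        smaller <- ifelse(
          !is.na(dup$count) & dup$count > 1,
          1L + as.integer(floor(stats::runif(nrow(dup)) * (dup$count - 1L))),
          NA_integer_
        )
        dup$count <- smaller
        pieces[[length(pieces) + 1]] <- dup
      }
    }
  }

  if (config$out_of_scope_count > 0) {
    k <- config$out_of_scope_count
    all_days <- seq(config$date_window[1], config$date_window[2], by = "day")
    pieces[[length(pieces) + 1]] <- tibble::tibble(
      record_id = sprintf("E%07da", seq_len(k)),
      country = "Spain",
      subnational = "",
      locality_id = sprintf("EU-L%d", seq_len(k)),
      latitude = snap6(stats::runif(k, 38, 52)),
      longitude = snap6(stats::runif(k, 0, 8)),
      date = sample(all_days, k, replace = TRUE),
      count = as.integer(sample(1:6, k, replace = TRUE))
    )
  }

  out <- dplyr::bind_rows(pieces)
  out <- dplyr::arrange(out, .data$date, .data$record_id)
  validate_records(out)
  out
}

# Rough representative coordinates per country, all inside the Americas
# scope polygon; used by the exact-accounting constructors.
country_coords <- function(country) {
  lookup <- list(
    "Bermuda" = c(32.30, -64.80), "Canada" = c(45.00, -75.00),
    "USA" = c(26.00, -81.00), "Mexico" = c(21.00, -89.00),
    "Belize" = c(17.50, -88.20), "Honduras" = c(15.80, -87.00),
    "Bonaire" = c(12.20, -68.30), "Brazil" = c(3.80, -51.20),
    "Colombia" = c(11.00, -74.00), "Cura\u00e7ao" = c(12.10, -68.90),
    "Ecuador" = c(-0.90, -90.90), "Guyana" = c(6.80, -58.20),
    "Suriname" = c(5.90, -57.00), "Venezuela" = c(10.90, -71.50),
    "Anguilla" = c(18.20, -63.00), "Aruba" = c(12.50, -70.00),
    "Bahamas" = c(24.00, -76.00), "Barbados" = c(13.10, -59.50),
    "Cayman Island" = c(19.30, -81.20), "Cuba" = c(21.50, -78.00),
    "Dominican Republic" = c(18.50, -69.90), "Granada" = c(12.10, -61.70),
    "Guadalupe" = c(16.20, -61.50), "Haiti" = c(18.50, -72.30),
    "Jamaica" = c(18.10, -77.30), "Puerto Rico" = c(18.20, -66.50),
    "Saint Kitts" = c(17.30, -62.70), "Saint Martin" = c(18.10, -63.10),
    "Trinidad and Tobago" = c(10.70, -61.20),
    "Turks and Caicos Islands" = c(21.80, -71.80),
    "Virgin Island" = c(18.30, -64.90)
  )
  coords <- lookup[[country]]
  if (is.null(coords)) c(15, -75) else coords
}

#' Manufacture a dataset matching target filter accounting exactly
#'
#' Builds, per target unit, a record set on which [run_filters()] reproduces
#' the requested accounting field-for-field: `n_final` numeric-count records
#' on distinct (locality, date) keys whose counts sum to `cum_individuals`
#' (one large count plus ones), `n_qualitative` presence-only records on
#' further distinct keys, and `n_duplicate` presence-only records colliding
#' with existing keys. A presence-only duplicate ranks below any numeric
#' count and its record id sorts after the group representative, so
#' representatives are never displaced. This makes the generator and the
#' filter pipeline mutual oracles, and allows published per-country
#' accounting tables to be replayed through the pipeline.
#'
#' @param targets Data frame with columns `country`, `n_record`,
#'   `n_duplicate`, `n_qualitative`, `n_final`, `cum_individuals`, and
#'   optionally `subnational`; one row per unit. Fields must satisfy the
#'   accounting identities `n_record = n_duplicate + n_qualitative + n_final`
#'   and `cum_individuals >= n_final` (0 only when `n_final` is 0).
#' @param seed Integer; only shuffles the output row order (the construction
#'   itself is deterministic).
#' @return An occurrence-record tibble.
#' @examples
#' targets <- tibble::tibble(
#'   country = "Mexico", n_record = 10, n_duplicate = 3,
#'   n_qualitative = 2, n_final = 5, cum_individuals = 50
#' )
#' glance(run_filters(generate_matching_accounting(targets)))
#' @export
generate_matching_accounting <- function(targets, seed = 1) {
  targets <- tibble::as_tibble(targets)
  needed <- c(
    "country", "n_record", "n_duplicate", "n_qualitative", "n_final",
    "cum_individuals"
  )
  missing <- setdiff(needed, names(targets))
  if (length(missing) > 0) {
    stop("targets missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"subnational" %in% names(targets)) targets$subnational <- ""
  num <- targets[setdiff(needed, "country")]
  if (any(unlist(num) < 0) || any(unlist(num) != floor(unlist(num)))) {
    stop("accounting targets must be non-negative integers", call. = FALSE)
  }
  bad <- targets$n_record !=
    targets$n_duplicate + targets$n_qualitative + targets$n_final
  if (any(bad)) {
    stop(
      "infeasible targets (n_record != n_duplicate + n_qualitative + n_final) for: ",
      paste(targets$country[bad], collapse = ", "),
      call. = FALSE
    )
  }
  bad <- targets$cum_individuals < targets$n_final |
    (targets$n_final == 0 & targets$cum_individuals > 0)
  if (any(bad)) {
    stop(
      "infeasible individuals totals for: ",
      paste(targets$country[bad], collapse = ", "),
      call. = FALSE
    )
  }
  bad <- targets$n_duplicate > 0 & targets$n_qualitative + targets$n_final == 0
  if (any(bad)) {
    stop(
      "duplicates need at least one clean record to collide with for: ",
      paste(targets$country[bad], collapse = ", "),
      call. = FALSE
    )
  }

  years <- 2010:2017
  pieces <- purrr::map(seq_len(nrow(targets)), function(u) {
    t <- targets[u, ]
    n_clean <- t$n_qualitative + t$n_final
    if (n_clean == 0) return(NULL)
    coords <- country_coords(t$country)
    k <- seq_len(n_clean)
    keys <- tibble::tibble(
      locality_id = sprintf("U%02d-L%05d", u, k),
      date = as.Date(sprintf(
        "%d-%02d-15", years[(k - 1) %% length(years) + 1],
        (k - 1) %% 12 + 1
      )),
      count = NA_integer_
    )
    if (t$n_final > 0) {
      keys$count[seq_len(t$n_final)] <- c(
        t$cum_individuals - (t$n_final - 1L),
        rep(1L, t$n_final - 1L)
      )
    }
    reps <- tibble::tibble(
      record_id = sprintf("U%02d-K%05d-a", u, k),
      country = t$country,
      subnational = t$subnational,
      locality_id = keys$locality_id,
      latitude = coords[1],
      longitude = coords[2],
      date = keys$date,
      count = keys$count
    )
    dups <- NULL
    if (t$n_duplicate > 0) {
      j <- seq_len(t$n_duplicate)
      hit <- (j - 1) %% n_clean + 1
      dups <- tibble::tibble(
        record_id = sprintf("U%02d-K%05d-z%04d", u, hit, j),
        country = t$country,
        subnational = t$subnational,
        locality_id = keys$locality_id[hit],
        latitude = coords[1],
        longitude = coords[2],
        date = keys$date[hit],
        count = NA_integer_
      )
    }
    dplyr::bind_rows(reps, dups)
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    stop("targets describe an empty dataset", call. = FALSE)
  }
  out <- with_seed(seed, out[sample.int(nrow(out)), ])
  validate_records(out)
  out
}

#' Manufacture breeding-season records matching target yearly totals
#'
#' The breeding analogue of [generate_matching_accounting()]: per target
#' unit, emits breeding-season (June) records in the first `n_years` window
#' years whose counts sum to `breeding_individuals`, so [breeding_table()]
#' on the result reproduces the unit's cumulative individuals, number of
#' years with data, percentage and per-year average exactly. (The spread of
#' individuals across years is an arbitrary construction — one large year
#' plus ones — so yearly SD/min/max are not matched.)
#'
#' @param targets Data frame with columns `country`, `breeding_individuals`,
#'   `n_years`, and optionally `subnational`.
#' @param window Integer years, default `2010:2018`.
#' @param seed Integer; shuffles output row order only.
#' @return An occurrence-record tibble of final-quality (numeric-count,
#'   duplicate-free) records.
#' @export
generate_matching_breeding <- function(targets, window = 2010:2018, seed = 1) {
  targets <- tibble::as_tibble(targets)
  needed <- c("country", "breeding_individuals", "n_years")
  missing <- setdiff(needed, names(targets))
  if (length(missing) > 0) {
    stop("targets missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"subnational" %in% names(targets)) targets$subnational <- ""
  if (any(targets$n_years < 1) || any(targets$n_years > length(window))) {
    stop("n_years must lie in 1..", length(window), call. = FALSE)
  }
  if (any(targets$breeding_individuals < targets$n_years)) {
    stop(
      "breeding_individuals must be at least n_years ",
      "(every year with data has >= 1 individual)",
      call. = FALSE
    )
  }
  pieces <- purrr::map(seq_len(nrow(targets)), function(u) {
    t <- targets[u, ]
    coords <- country_coords(t$country)
    yrs <- window[seq_len(t$n_years)]
    tibble::tibble(
      record_id = sprintf("B%02d-Y%04d", u, yrs),
      country = t$country,
      subnational = t$subnational,
      locality_id = sprintf("B%02d-L%04d", u, yrs),
      latitude = coords[1],
      longitude = coords[2],
      date = as.Date(sprintf("%d-06-15", yrs)),
      count = as.integer(c(
        t$breeding_individuals - (t$n_years - 1L),
        rep(1L, t$n_years - 1L)
      ))
    )
  })
  out <- dplyr::bind_rows(pieces)
  out <- with_seed(seed, out[sample.int(nrow(out)), ])
  validate_records(out)
  out
}
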