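test_that("records are assigned to regions and sub-country units", {
  recs <- make_records(
    c("A", "B", "C", "D", "E"),
    country = c("Mexico", "Mexico", "Bonaire", "USA", "Atlantis"),
    subnational = c("Yucatán", "Jalisco", "", "Florida", "")
  )
  out <- suppressMessages(assign_region(recs))
  expect_identical(
    out$region,
    c(
      "North America", "North America", "South America", "North America",
      "Unassigned"
    )
  )
  expect_identical(
    out$unit,
    c(
      "Mexico-Yucatan Peninsula", "Mexico-Central", "Bonaire",
      "US-Gulf of Mexico/Florida", "Atlantis"
    )
  )
  expect_message(assign_region(recs), "Unassigned")
})

test_that("sub-country polygon fallback catches records without codes", {
  scheme <- region_scheme(
    c(Testland = "South America"),
    subcountry_rules = list(Testland = list(
      north = list(polygon = cbind(c(-1, 1, 1, -1), c(0, 0, 1, 1))),
      south = NULL
    ))
  )
  recs <- make_records(
    c("A", "B"),
    country = "Testland",
    latitude = c(0.5, -0.5), longitude = 0
  )
  out <- assign_region(recs, scheme)
  expect_identical(out$unit, c("north", "south"))
})

test_that("decades are labelled within the analysis window only", {
  expect_identical(
    decade_of(as.Date(c("1969-12-31", "1970-01-01", "2018-10-31"))),
    c("1960s", "1970s", "2010s")
  )
  expect_error(decade_of(as.Date("2018-11-01")), "outside the analysis window")
  expect_error(decade_of(as.Date("1959-12-31")), "outside the analysis window")
})

test_that("unit summaries equal an independent group-and-sum pass", {
  recs <- random_dataset(21)
  fit <- run_filters(recs)
  units <- summarize_units(fit, level = "country")

  # brute-force oracle over the ledger, bypassing the dplyr pipeline
  ledger <- fit$ledger[fit$ledger$status != "scoped_out", ]
  for (ctry in unique(ledger$country)) {
    sub <- ledger[ledger$country == ctry, ]
    row <- units[units$unit == ctry, ]
    expect_identical(row$n_record, nrow(sub))
    expect_identical(row$n_duplicate, sum(sub$status == "duplicate"))
    expect_identical(row$n_qualitative, sum(sub$status == "presence_only"))
    expect_identical(row$n_final, sum(sub$status == "final"))
    expect_identical(
      row$cum_individuals,
      sum(sub$count[sub$status == "final"])
    )
    expect_identical(
      row$first_record_year,
      min(as.integer(format(sub$date[sub$status == "final"], "%Y")))
    )
  }

  # region rows are the sums of their member countries
  regions <- summarize_units(fit, level = "region")
  by_region <- tapply(units$n_final, units$region, sum)
  expect_identical(
    as.integer(by_region[regions$region]),
    regions$n_final
  )
  expect_identical(sum(units$cum_individuals), sum(regions$cum_individuals))
})

test_that("a single-record dataset yields a single one-record unit", {
  recs <- make_records("S1", country = "Cuba", count = 23L)
  units <- summarize_units(recs)
  expect_identical(nrow(units), 1L)
  expect_identical(units$n_final, 1L)
  expect_identical(units$cum_individuals, 23L)
  expect_identical(units$first_record_year, 2015L)
})

test_that("decade summaries partition the unit totals", {
  recs <- run_filters(random_dataset(22))$records
  decades <- summarize_decades(recs)
  units <- summarize_units(recs)
  rolled <- tapply(decades$cum_individuals, decades$unit, sum)
  expect_identical(
    as.integer(rolled[units$unit]),
    units$cum_individuals
  )
  # records confined to 2012-2017 occupy only the 2010s bin
  recent <- make_records(
    c("A", "B"),
    date = as.Date(c("2012-03-01", "2017-09-30")),
    locality_id = c("L1", "L2")
  )
  expect_identical(unique(summarize_decades(recent)$decade), "2010s")
})

test_that("record days count distinct dates and never exceed record counts", {
  three <- make_records(
    c("A", "B", "C"),
    locality_id = c("L1", "L2", "L3"),
    date = as.Date(c("2015-06-01", "2015-06-01", "2015-06-02"))
  )
  expect_identical(record_days(three)$n_record_days, 2L)

  recs <- run_filters(random_dataset(23))$records
  days <- record_days(recs)
  units <- summarize_units(recs)
  # oracle: set of dates per country
  for (ctry in units$unit) {
    expect_identical(
      days$n_record_days[days$unit == ctry],
      length(unique(recs$date[recs$country == ctry]))
    )
  }
  expect_true(all(days$n_record_days <= units$n_final[match(days$unit, units$unit)]))
})

test_that("individuals-per-record index is the tally quotient and >= 1", {
  ten <- make_records(
    sprintf("R%02d", 1:10),
    locality_id = sprintf("L%02d", 1:10),
    count = c(991L, rep(1L, 9))
  )
  idx <- individuals_per_record_index(ten)
  expect_identical(idx$individuals_per_record, 100)

  ones <- make_records(c("A", "B"), locality_id = c("L1", "L2"), count = 1L)
  expect_identical(individuals_per_record_index(ones)$individuals_per_record, 1)

  recs <- run_filters(random_dataset(24))$records
  idx <- individuals_per_record_index(recs)
  expect_true(all(idx$individuals_per_record >= 1))
  expect_equal(
    idx$individuals_per_record,
    idx$cum_individuals / idx$n_records
  )
  # presence-only records are rejected
  recs$count[1] <- NA_integer_
  expect_error(individuals_per_record_index(recs), "quantitative")
})

test_that("range classification matches a closed-form square membership", {
  set.seed(202)
  n <- 1000
  recs <- make_records(
    sprintf("P%04d", seq_len(n)),
    latitude = runif(n, -1, 2),
    longitude = runif(n, -1, 2)
  )
  got <- classify_against_range(recs, unit_square)$inside_range
  oracle <- recs$longitude >= 0 & recs$longitude <= 1 &
    recs$latitude >= 0 & recs$latitude <= 1
  expect_identical(got, oracle)
})

test_that("ray casting agrees with mgcv::in.out on interior points of a concave ring", {
  set.seed(203)
  # concave "L" shape
  ring <- cbind(
    c(0, 4, 4, 2, 2, 0),
    c(0, 0, 1, 1, 3, 3)
  )
  x <- runif(500, -0.5, 4.5)
  y <- runif(500, -0.5, 3.5)
  got <- point_in_polygon(x, y, ring)
  closed <- rbind(ring, ring[1, ])
  oracle <- as.logical(mgcv::in.out(closed, cbind(x, y)))
  # random points never hit the boundary, where conventions may differ
  expect_identical(got, oracle)
})

test_that("boundary and vertex points classify as inside", {
  expect_true(all(point_in_polygon(
    c(0, 0.5, 1, 1), c(0, 0, 0.5, 1), unit_square
  )))
  expect_false(point_in_polygon(1.0000001, 0.5, unit_square))
  # centroid of a convex polygon is inside
  hex <- cbind(cos(seq(0, 5) * pi / 3), sin(seq(0, 5) * pi / 3))
  expect_true(point_in_polygon(mean(hex[, 1]), mean(hex[, 2]), hex))
})

test_that("multipolygon membership is the union of its rings", {
  two <- list(unit_square, unit_square + 10)
  expect_identical(
    point_in_polygon(c(0.5, 10.5, 5), c(0.5, 10.5, 5), two),
    c(TRUE, TRUE, FALSE)
  )
})
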