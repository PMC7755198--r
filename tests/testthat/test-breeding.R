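test_that("season splits at April-August by month only", {
  expect_identical(
    season_of(as.Date(c(
      "2015-04-01", "2015-08-31", "2015-06-15",
      "2015-09-01", "2015-03-31", "2015-12-25"
    ))),
    c(rep("breeding", 3), rep("nonbreeding", 3))
  )
})

test_that("breeding percentages are exact shares of the included units", {
  two <- make_records(
    c("A", "B"),
    country = c("Cuba", "Bahamas"),
    locality_id = c("L1", "L2"),
    latitude = c(21.5, 24.0),
    count = c(300L, 700L)
  )
  tab <- breeding_table(two)
  expect_equal(sort(tab$pct_breeding), c(30, 70))
  expect_equal(sum(tab$pct_breeding), 100)

  one <- breeding_table(two[1, ])
  expect_equal(one$pct_breeding, 100)
})

test_that("units observed only outside the breeding season change nothing", {
  base <- make_records(
    c("A", "B"),
    country = c("Cuba", "Bahamas"),
    locality_id = c("L1", "L2"),
    count = c(300L, 700L)
  )
  winter <- make_records(
    "C",
    country = "Haiti", locality_id = "L3",
    date = as.Date("2015-12-01"), count = 9999L
  )
  with_extra <- breeding_table(dplyr::bind_rows(base, winter))
  expect_identical(nrow(with_extra), 2L)
  expect_equal(
    with_extra$pct_breeding,
    breeding_table(base)$pct_breeding
  )
})

test_that("percentages and the critical flag are scale invariant", {
  recs <- run_filters(random_dataset(31))$records
  tab1 <- breeding_table(recs)
  scaled <- dplyr::mutate(recs, count = count * 7L)
  tab2 <- breeding_table(scaled)
  expect_equal(tab1$pct_breeding, tab2$pct_breeding)
  expect_identical(
    classify_critical(tab1, "Ecuador"),
    classify_critical(tab2, "Ecuador")
  )
})

test_that("a window without breeding-season records is an error", {
  winter <- make_records("A", date = as.Date("2015-01-15"))
  expect_error(breeding_table(winter), "no breeding-season records")
})

test_that("yearly series feed avg/SD/min/max with the NA rules", {
  # constant three-year series
  recs <- make_records(
    c("A", "B", "C"),
    locality_id = c("L1", "L2", "L3"),
    date = as.Date(c("2011-06-01", "2012-06-01", "2013-06-01")),
    count = 40L
  )
  tab <- breeding_table(recs)
  expect_identical(tab$n_years, 3L)
  expect_equal(tab$avg_per_year, 40)
  expect_equal(tab$sd_per_year, 0)
  expect_equal(tab$min_year_total, 40)
  expect_equal(tab$max_year_total, 40)

  # single year: SD and min/max do not apply
  tab1 <- breeding_table(recs[1, ])
  expect_identical(tab1$n_years, 1L)
  expect_equal(tab1$avg_per_year, 40)
  expect_true(is.na(tab1$sd_per_year))
  expect_true(is.na(tab1$min_year_total))

  # two years: min/max defined, SD not
  tab2 <- breeding_table(recs[1:2, ])
  expect_identical(tab2$n_years, 2L)
  expect_true(is.na(tab2$sd_per_year))
  expect_equal(tab2$min_year_total, 40)
  expect_equal(tab2$max_year_total, 40)

  # avg always between min and max when defined
  big <- breeding_table(run_filters(random_dataset(32))$records)
  ok <- !is.na(big$min_year_total)
  expect_true(all(big$min_year_total[ok] <= big$avg_per_year[ok]))
  expect_true(all(big$avg_per_year[ok] <= big$max_year_total[ok]))
})

test_that("yearly series omit empty years rather than storing zeros", {
  recs <- make_records(
    c("A", "B"),
    locality_id = c("L1", "L2"),
    date = as.Date(c("2010-06-01", "2014-06-01")),
    count = c(5L, 7L)
  )
  series <- yearly_breeding_series(recs)
  expect_identical(series$year, c(2010L, 2014L))
  expect_identical(series$cum_individuals, c(5L, 7L))
})

test_that("critical classification is inclusive, alphabetical and validated", {
  recs <- dplyr::bind_rows(
    make_records("A", country = "Ecuador", locality_id = "L1", count = 100L),
    make_records("B", country = "Cuba", locality_id = "L2", count = 500L),
    make_records("C", country = "Haiti", locality_id = "L3", count = 20L),
    make_records("D", country = "Venezuela", locality_id = "L4", count = 380L)
  )
  tab <- breeding_table(recs)
  expect_identical(
    classify_critical(tab, "Ecuador"),
    c("Cuba", "Ecuador", "Venezuela")
  )
  # the reference always classifies itself, even when it holds the maximum
  expect_identical(classify_critical(tab, "Cuba"), "Cuba")
  expect_error(classify_critical(tab, "Bahamas"), "not in the table")

  flagged <- flag_critical(tab, "Ecuador")
  expect_identical(
    sort(flagged$unit[flagged$is_critical]),
    classify_critical(tab, "Ecuador")
  )
  # equal percentages: everyone meets the threshold
  even <- breeding_table(make_records(
    c("A", "B"),
    country = c("Cuba", "Haiti"), locality_id = c("L1", "L2"), count = 50L
  ))
  expect_identical(length(classify_critical(even, "Cuba")), 2L)
})

test_that("configured abundance shares are recovered within sampling error", {
  # near-Poisson flocks and one busy decade keep the sampling error on the
  # Venezuela share below half a percentage point
  colonies <- default_colonies()
  colonies$dispersion <- 50
  cfg <- synthetic_config(
    colonies = colonies,
    effort = c("2010s" = 3000),
    duplicate_prob = 0, presence_only_prob = 0, out_of_scope_count = 0,
    seed = 99
  )
  recs <- generate_occurrences(cfg)
  tab <- breeding_table(run_filters(recs)$records)

  breeding_mean <- colonies$mean_count * colonies$breeding_multiplier
  expected_share <- 100 * breeding_mean / sum(breeding_mean)
  got <- tab$pct_breeding[match(
    c("Venezuela", "Mexico-Yucatan Peninsula", "Ecuador"),
    tab$unit
  )]
  want <- expected_share[match(
    c("Los Olivitos", "Ria Lagartos", "Galapagos"),
    colonies$name
  )]
  expect_lt(max(abs(got - want)), 0.5)
})
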