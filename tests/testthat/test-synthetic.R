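test_that("generation is deterministic under seed and leaves the RNG alone", {
  cfg <- synthetic_config(seed = 5)
  a <- generate_occurrences(cfg)
  b <- generate_occurrences(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_occurrences(synthetic_config(seed = 6))))

  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_occurrences(cfg))
  expect_identical(runif(3), before)
})

test_that("a clean configuration produces nothing for the filters to remove", {
  cfg <- synthetic_config(
    duplicate_prob = 0, presence_only_prob = 0, out_of_scope_count = 0,
    seed = 12
  )
  recs <- generate_occurrences(cfg)
  a <- run_filters(recs)$accounting
  expect_identical(a$n_scoped_out, 0L)
  expect_identical(a$n_duplicate, 0L)
  expect_identical(a$n_qualitative, 0L)
  expect_identical(a$n_final, nrow(recs))
})

test_that("duplicate_prob 1 duplicates every base checklist exactly once", {
  cfg <- synthetic_config(
    effort = c("2000s" = 30, "2010s" = 50),
    duplicate_prob = 1, presence_only_prob = 0.2, out_of_scope_count = 0,
    seed = 13
  )
  recs <- generate_occurrences(cfg)
  a <- run_filters(recs)$accounting
  expect_identical(a$n_duplicate, a$n_clean)
  expect_identical(nrow(recs), 2L * a$n_clean)
})

test_that("the presence-only rate is recovered within 3 standard errors", {
  p <- 0.1
  cfg <- synthetic_config(
    colonies = default_colonies()[2:5, ],
    effort = c(
      "1960s" = 400, "1970s" = 400, "1980s" = 400,
      "1990s" = 400, "2000s" = 400, "2010s" = 400
    ),
    duplicate_prob = 0, presence_only_prob = p, out_of_scope_count = 0,
    seed = 14
  )
  recs <- generate_occurrences(cfg)
  a <- run_filters(recs)$accounting
  expect_gt(a$n_clean, 5000)
  se <- sqrt(p * (1 - p) / a$n_clean)
  expect_lt(abs(a$n_qualitative / a$n_clean - p), 3 * se)
})

test_that("the duplication rate is recovered within 3 standard errors", {
  q <- 0.3
  cfg <- synthetic_config(
    colonies = default_colonies()[2:5, ],
    effort = c("2000s" = 800, "2010s" = 800),
    duplicate_prob = q, presence_only_prob = 0, out_of_scope_count = 0,
    seed = 15
  )
  a <- run_filters(generate_occurrences(cfg))$accounting
  se <- sqrt(q * (1 - q) / a$n_clean)
  expect_lt(abs(a$n_duplicate / a$n_clean - q), 3 * se)
})

test_that("the default config covers all four regions deterministically", {
  recs <- generate_occurrences(synthetic_config())
  regions <- suppressMessages(assign_region(recs))$region
  expect_true(all(
    c("North America", "South America", "Caribbean") %in% regions
  ))
  # byte-identical TSV across runs of the same config
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_records(generate_occurrences(synthetic_config()), p1)
  write_records(generate_occurrences(synthetic_config()), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("exact-accounting targets are reproduced by the pipeline", {
  targets <- tibble::tibble(
    country = c("Mexico", "Cuba", "Guyana"),
    n_record = c(10L, 25L, 4L),
    n_duplicate = c(3L, 10L, 0L),
    n_qualitative = c(2L, 5L, 0L),
    n_final = c(5L, 10L, 4L),
    cum_individuals = c(50L, 1000L, 4L)
  )
  recs <- generate_matching_accounting(targets, seed = 2)
  fit <- run_filters(recs)
  units <- summarize_units(fit)
  got <- units[match(targets$country, units$unit), ]
  expect_identical(got$n_record, targets$n_record)
  expect_identical(got$n_duplicate, targets$n_duplicate)
  expect_identical(got$n_qualitative, targets$n_qualitative)
  expect_identical(got$n_final, targets$n_final)
  expect_identical(got$cum_individuals, targets$cum_individuals)

  # zero-duplicate zero-qualitative targets collapse Record onto Record_final
  simple <- tibble::tibble(
    country = "Aruba", n_record = 6L, n_duplicate = 0L,
    n_qualitative = 0L, n_final = 6L, cum_individuals = 60L
  )
  a <- glance(run_filters(generate_matching_accounting(simple)))
  expect_identical(a$n_record, a$n_final)
})

test_that("infeasible accounting targets are rejected", {
  base <- tibble::tibble(
    country = "Cuba", n_record = 10L, n_duplicate = 3L,
    n_qualitative = 2L, n_final = 5L, cum_individuals = 50L
  )
  broken <- dplyr::mutate(base, n_record = 11L)
  expect_error(generate_matching_accounting(broken), "infeasible")
  starved <- dplyr::mutate(base, cum_individuals = 4L)
  expect_error(generate_matching_accounting(starved), "infeasible")
  orphan <- dplyr::mutate(base,
    n_duplicate = 10L, n_qualitative = 0L, n_final = 0L, cum_individuals = 0L
  )
  expect_error(generate_matching_accounting(orphan), "collide")
  fractional <- dplyr::mutate(base, cum_individuals = 50.5)
  expect_error(generate_matching_accounting(fractional), "integers")
})

test_that("breeding targets are reproduced by the breeding table", {
  targets <- tibble::tibble(
    country = c("Cuba", "Ecuador"),
    breeding_individuals = c(700L, 9L),
    n_years = c(7L, 3L)
  )
  tab <- breeding_table(generate_matching_breeding(targets))
  got <- tab[match(targets$country, tab$unit), ]
  expect_identical(got$breeding_individuals, targets$breeding_individuals)
  expect_identical(got$n_years, targets$n_years)
  expect_equal(got$pct_breeding, 100 * c(700, 9) / 709)

  expect_error(
    generate_matching_breeding(dplyr::mutate(targets, n_years = 10L)),
    "n_years"
  )
  expect_error(
    generate_matching_breeding(dplyr::mutate(targets, breeding_individuals = 2L)),
    "at least n_years"
  )
})

test_that("YAML configuration round-trips through read and write", {
  cfg <- synthetic_config(duplicate_prob = 0.4, seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back$duplicate_prob, 0.4)
  expect_identical(back$seed, 77L)
  expect_equal(
    as.data.frame(back$colonies), as.data.frame(cfg$colonies)
  )
  expect_identical(generate_occurrences(back), generate_occurrences(cfg))
})

test_that("invalid generator parameters are configuration errors", {
  expect_error(synthetic_config(duplicate_prob = 1.2), "probabilities")
  expect_error(synthetic_config(presence_only_prob = -0.1), "probabilities")
  bad <- default_colonies()
  bad$mean_count[1] <- 0.5
  expect_error(synthetic_config(colonies = bad), "mean_count")
})
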