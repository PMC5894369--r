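test_that("uniform weights with no jitter spread a quintile evenly", {
  p <- test_profiles(quintile_smokers = list(rep(1, 5)))
  s <- synthesize_age_structure(p, weights = "uniform", jitter = 0, seed = 7)
  one <- dplyr::filter(s, quintile == 1)
  expect_equal(nrow(one), 15)
  expect_equal(one$smokers, rep(1 / 15, 15))
})

test_that("age allocation conserves quintile totals for any jitter and seed", {
  p <- load_country_profiles()
  for (jit in c(0, 0.05, 0.5)) {
    s <- synthesize_age_structure(p, jitter = jit, seed = 11)
    got <- s |>
      dplyr::group_by(country, quintile) |>
      dplyr::summarise(smokers = sum(smokers), .groups = "drop") |>
      dplyr::arrange(country, quintile)
    want <- p |>
      tibble::as_tibble() |>
      dplyr::select(country, smokers_by_quintile) |>
      tidyr::unnest_longer(smokers_by_quintile, values_to = "smokers") |>
      dplyr::group_by(country) |>
      dplyr::mutate(quintile = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::arrange(country, quintile)
    expect_equal(got$smokers, want$smokers, tolerance = 1e-9)
  }
})

test_that("generation is deterministic per seed and country-order invariant", {
  p <- load_country_profiles()
  a <- synthesize_age_structure(p, jitter = 0.2, seed = 42)
  b <- synthesize_age_structure(p, jitter = 0.2, seed = 42)
  expect_identical(a, b)
  c <- synthesize_age_structure(p, jitter = 0.2, seed = 43)
  expect_false(isTRUE(all.equal(a$smokers, c$smokers)))
  # per-country substreams: reversing the row order changes nothing per country
  d <- synthesize_age_structure(p[rev(seq_len(nrow(p))), ], jitter = 0.2, seed = 42)
  d <- dplyr::arrange(d, match(country, a$country), quintile, age_band)
  a2 <- dplyr::arrange(a, country, quintile, age_band)
  d2 <- dplyr::arrange(d, country, quintile, age_band)
  expect_equal(a2$smokers, d2$smokers)
})

test_that("default triangular weights peak at 35-39 and vanish above 84", {
  p <- test_profiles()
  s <- synthesize_age_structure(p, seed = 1)
  by_band <- s |>
    dplyr::group_by(age_band) |>
    dplyr::summarise(smokers = sum(smokers), .groups = "drop")
  expect_equal(by_band$age_band[which.max(by_band$smokers)], "35-39")
  expect_equal(by_band$smokers[by_band$age_band == "85-89"], 0)
  expect_error(synthesize_age_structure(p, weights = rep(0, 15)), "zero")
})

test_that("future cohort is off by default, identity at fraction 1", {
  p <- load_country_profiles()
  f0 <- synthesize_future_cohort(p, initiation_fraction = 0)
  expect_true(all(f0$future_smokers == 0))
  f1 <- synthesize_future_cohort(p, initiation_fraction = 1)
  got <- dplyr::arrange(f1, country, quintile)$future_smokers
  want <- p |>
    tibble::as_tibble() |>
    dplyr::select(country, smokers_by_quintile) |>
    dplyr::arrange(country) |>
    dplyr::pull(smokers_by_quintile) |>
    unlist()
  expect_equal(got, want)
  expect_error(synthesize_future_cohort(p, initiation_fraction = 2), "initiation")
})

test_that("quintile income samples respect truncation, mean, and Gini", {
  p <- test_profiles(gini = 0.46, mean_income = 10000)
  # degenerate: no inequality means everyone earns the mean
  p0 <- test_profiles(gini = 0, mean_income = 1000)
  expect_equal(sample_quintile_incomes(p0, 3, 50, seed = 1), rep(1000, 50))
  # quintile 5 support sits above quintile 1 support
  lo <- sample_quintile_incomes(p, 1, 2000, seed = 2)
  hi <- sample_quintile_incomes(p, 5, 2000, seed = 2)
  expect_gte(min(hi), max(lo))
  expect_error(sample_quintile_incomes(p, 6, 10), "quintile")
  # pooled moments: mean within 1% and empirical Gini within 0.01 at n = 1e5
  n <- 2e4
  pooled <- unlist(lapply(1:5, function(q) sample_quintile_incomes(p, q, n, seed = q)))
  expect_equal(mean(pooled), 10000, tolerance = 0.01)
  expect_equal(empirical_gini(pooled), 0.46, tolerance = 0.01)
})
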