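test_that("the cessation schedule hits the interval anchors and is monotone", {
  s <- fit_life_year_schedule()
  ly <- function(b) s$life_years_per_quitter[s$age_band == b]
  expect_equal(ly("20-24"), 10)
  expect_equal(ly("15-19"), 10)   # constant extrapolation below the first knot
  expect_equal(ly("35-39"), 9)
  expect_equal(ly("75-79"), 3)
  expect_equal(ly("85-89"), 3)    # constant extrapolation above the last knot
  expect_true(all(diff(s$life_years_per_quitter) <= 1e-12))
  expect_true(all(s$life_years_per_quitter >= 0))
  # bands wholly inside a knot interval stay near the interval value
  expect_lt(abs(ly("50-54") - 6), 1.5)
  expect_lt(abs(ly("30-34") - 9), 1.5)
  bad <- tibble::tibble(age = c(22.5, 37.5, 55, 75), years_gained = c(10, 9, 9.5, 3))
  expect_error(fit_life_year_schedule(bad), "decreasing")
})

test_that("life years gained multiply quitters by the schedule", {
  q <- tibble::tibble(country = "X", age_band = c("20-24", "75-79"),
                      quintile = 1, quitters = c(1.0, 0.5))
  out <- life_years_gained(q)
  expect_equal(out$life_years, c(1.0 * 10, 0.5 * 3))
  out0 <- life_years_gained(dplyr::mutate(q, quitters = 0))
  expect_equal(out0$life_years, c(0, 0))
})

test_that("deaths averted decay with age like the benefit schedule", {
  q <- tibble::tibble(country = "X", age_band = c("20-24", "75-79"),
                      quintile = 1, quitters = 1.0)
  out <- deaths_averted(q, death_risk = 0.5)
  expect_equal(out$deaths_averted, c(1.0 * 0.5 * 10 / 10, 1.0 * 0.5 * 3 / 10))
  expect_equal(deaths_averted(q, death_risk = 0)$deaths_averted, c(0, 0))
  expect_true(all(out$deaths_averted <= out$quitters))
})

test_that("per-quitter life years favour the young", {
  s <- fit_life_year_schedule()
  ly <- function(b) s$life_years_per_quitter[s$age_band == b]
  expect_gte(ly("25-29"), ly("60-64"))
})

test_that("death apportionment conserves totals for arbitrary mixes", {
  deaths <- tibble::tibble(country = "X", quintile = 1:3,
                           deaths_averted = c(1.0, 0.4, 0.2))
  even <- tibble::tibble(country = "X",
                         disease = c("copd", "stroke", "heart_disease", "cancers"),
                         mix_share = rep(0.25, 4))
  out <- apportion_deaths(deaths, even)
  expect_equal(out$disease_deaths[out$quintile == 1], rep(0.25, 4))
  all_copd <- dplyr::mutate(even, mix_share = c(1, 0, 0, 0))
  out2 <- apportion_deaths(deaths, all_copd)
  expect_equal(sum(out2$disease_deaths[out2$disease == "copd"]), sum(deaths$deaths_averted))
  # property: conservation under random mixes (summation oracle)
  set.seed(99)
  for (i in 1:10) {
    w <- rgamma(4, 1)
    mix <- dplyr::mutate(even, mix_share = w / sum(w))
    out_i <- apportion_deaths(deaths, mix) |>
      dplyr::group_by(quintile) |>
      dplyr::summarise(d = sum(disease_deaths), .groups = "drop")
    expect_equal(out_i$d, deaths$deaths_averted, tolerance = 1e-12)
  }
  badmix <- dplyr::mutate(even, mix_share = rep(0.3, 4))
  expect_error(apportion_deaths(deaths, badmix), "sum to 1")
})
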