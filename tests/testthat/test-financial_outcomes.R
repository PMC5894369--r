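test_that("lognormal income model matches the Gini and the mean in closed form", {
  m <- lognormal_from_gini(0.46, 10000)
  expect_equal(m$sigma, sqrt(2) * qnorm(1.46 / 2), tolerance = 1e-12)
  expect_equal(m$sigma, 0.8666, tolerance = 1e-3)
  expect_equal(m$mu, log(10000) - 0.3753, tolerance = 1e-4)
  # round trips to machine precision
  expect_equal(gini_lognormal(m$sigma), 0.46, tolerance = 1e-12)
  expect_equal(exp(m$mu + m$sigma^2 / 2), 10000, tolerance = 1e-9)
  # degenerate case
  m0 <- lognormal_from_gini(0, 500)
  expect_equal(m0$sigma, 0)
  expect_error(lognormal_from_gini(1, 100), "gini")
  # Monte-Carlo cross-check of the closed-form Gini
  x <- withr::with_seed(5, rlnorm(2e5, m$mu, m$sigma))
  expect_equal(empirical_gini(x), 0.46, tolerance = 0.01)
})

test_that("out-of-pocket share is the uncovered cost fraction, with overrides", {
  p <- load_country_profiles()
  os <- oop_share(p)
  india <- dplyr::filter(os, country == "India", quintile == 1, disease == "copd")
  expect_equal(india$oop_share, 1 - 0.14 * 0.40)
  full <- oop_share(test_profiles(coverage_fraction = 1, public_cost_share = 1))
  expect_true(all(full$oop_share == 0))
  none <- oop_share(test_profiles(coverage_fraction = 0))
  expect_true(all(none$oop_share == 1))
  # Mexico's scheme: poorest two quintiles fully covered for COPD only
  ov <- load_coverage_overrides()
  os2 <- oop_share(p, ov)
  mex <- dplyr::filter(os2, country == "Mexico")
  expect_equal(mex$oop_share[mex$quintile == 1 & mex$disease == "copd"], 0)
  expect_equal(mex$oop_share[mex$quintile == 1 & mex$disease == "cancers"], 1)
  expect_equal(mex$oop_share[mex$quintile == 4 & mex$disease == "stroke"],
               1 - 0.82 * 0.70)
  # other countries untouched by the override table
  expect_equal(dplyr::filter(os2, country != "Mexico"),
               dplyr::filter(os, country != "Mexico"))
})

test_that("costs averted combine deaths, unit costs and oop shares", {
  d <- tibble::tibble(country = "X", quintile = 1,
                      disease = c("a", "b"), disease_deaths = c(0.001, 0.002))
  uc <- tibble::tibble(country = "X", disease = c("a", "b"),
                       unit_cost = c(4000, 2500))
  os <- tibble::tibble(country = "X", quintile = 1, disease = c("a", "b"),
                       oop_share = c(0.5, 1.0))
  out <- costs_averted(d, uc, os)
  expect_equal(out$cost_averted_total, 0.001 * 4000 + 0.002 * 2500)  # 9.0
  expect_equal(out$cost_averted_oop, 0.001 * 4000 * 0.5 + 0.002 * 2500)  # 7.0
  out0 <- costs_averted(d, uc, dplyr::mutate(os, oop_share = 0))
  expect_equal(out0$cost_averted_oop, 0)
  expect_error(costs_averted(d, dplyr::mutate(uc, unit_cost = -1), os), "unit costs")
})

test_that("catastrophic expenditure probability agrees with the Monte-Carlo oracle", {
  model <- lognormal_from_gini(0.42, 6000)
  p <- test_profiles(gini = 0.42, mean_income = 6000)
  n <- 1e6
  for (q in c(1, 3, 5)) {
    cost <- 450
    income <- sample_quintile_incomes(p, q, n, seed = 100 + q)
    hit <- 0.1 * income < cost
    p_mc <- mean(hit)
    se <- sqrt(p_mc * (1 - p_mc) / n)
    got <- catastrophic_averted(1, cost, model, q)
    expect_lt(abs(got - p_mc), max(3 * se, 1e-6))
  }
  expect_equal(catastrophic_averted(1, 0, model, 1), 0)
  # degenerate income: everyone at the mean, cost above the threshold
  m0 <- lognormal_from_gini(0, 1000)
  expect_equal(catastrophic_averted(2, 200, m0, 3), 2)
  expect_equal(catastrophic_averted(2, 50, m0, 3), 0)
})

test_that("impoverishment probability agrees with the Monte-Carlo oracle", {
  model <- lognormal_from_gini(0.42, 6000)
  p <- test_profiles(gini = 0.42, mean_income = 6000)
  line <- 1.90 * 365
  n <- 1e6
  for (q in c(1, 2)) {
    cost <- 600
    income <- sample_quintile_incomes(p, q, n, seed = 200 + q)
    hit <- income >= line & income - cost < line
    p_mc <- mean(hit)
    se <- sqrt(max(p_mc * (1 - p_mc), 1e-12) / n)
    got <- poverty_averted(1, cost, model, q)
    expect_lt(abs(got - p_mc), max(3 * se, 1e-6))
  }
  expect_equal(poverty_averted(1, 0, model, 1), 0)
  # everyone already below the line: nobody can newly fall below it
  poor <- lognormal_from_gini(0, 300)
  expect_equal(poverty_averted(1, 500, poor, 1), 0)
})

test_that("catastrophic risk is non-increasing in quintile for fixed cost", {
  model <- lognormal_from_gini(0.5, 9000)
  probs <- catastrophic_averted(rep(1, 5), 400, model, 1:5)
  expect_true(all(diff(probs) <= 1e-12))
})

test_that("excise arithmetic reproduces the published per-pack increases and rates", {
  expect_equal(excise_increase_for_price_rise(9.2, 0.5), 4.6)   # India
  expect_equal(excise_increase_for_price_rise(2.2, 0.5), 1.1)   # Colombia
  expect_equal(excise_increase_for_price_rise(7.1, 0), 0)
  expect_equal(excise_rate_increase_pct(2.8, 0.508, 0.5), 197)  # China
  expect_equal(excise_rate_increase_pct(10.3, 0.821, 0.5), 122) # Turkey
  expect_equal(excise_rate_increase_pct(4, 0.5, 0.5, excise_fraction_of_tax = 1), 100)
  expect_error(excise_rate_increase_pct(4, 0, 0.5), "tax_share")
})

test_that("extra tax revenue matches the hand-computed example and is positive", {
  # 1M smokers, 10 sticks/day, $4/pack, 50% tax share, -0.4, +50% price:
  # before 365, after 0.9 x 164.25 x 4 (per million smokers, $m)
  got <- extra_tax_revenue(1, 10, 4, 0.5, -0.4, 0.5)
  expect_equal(got, 0.9 * 164.25 * 4 - 365, tolerance = 1e-9)
  expect_equal(got, 226.3, tolerance = 1e-3)
  expect_equal(extra_tax_revenue(1, 10, 4, 0.5, -0.4, 0), 0)
  # no behavioural response: pure price effect of the excise increase
  expect_equal(extra_tax_revenue(1, 10, 4, 0.5, 0, 0.5), 1 * 182.5 * 0.5 * 4)
  # the higher tax per pack dominates the demand loss throughout the
  # operative region (consumption responses up to ~50%)
  for (e in c(-0.2, -0.6, -1)) {
    for (dp in c(0.25, 0.5)) {
      expect_gt(extra_tax_revenue(1, 10, 4, 0.5, e, dp), 0)
    }
  }
  expect_gt(extra_tax_revenue(1, 10, 4, 0.5, -0.6, 1), 0)
  # at the extreme corner (unit elasticity, doubled price) the surviving
  # consumption is too small to pay for itself: revenue genuinely falls
  expect_lt(extra_tax_revenue(1, 10, 4, 0.5, -1, 1), 0)
})
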