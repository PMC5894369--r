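test_that("the anchored matrix pins both published anchor cells", {
  m <- build_elasticity_matrix()
  cell <- function(g, q) m$elasticity[m$age_group == g & m$quintile == q]
  expect_equal(cell("15-24", 1), -1.27)
  expect_equal(cell("25+", 5), -0.24)
  # closed-form geometric construction: old-bottom is the young anchor halved,
  # with constant per-quintile ratio (0.24/0.635)^(1/4)
  expect_equal(cell("25+", 1), -0.635)
  r <- (0.24 / 0.635)^(1 / 4)
  old <- vapply(1:5, function(q) cell("25+", q), numeric(1))
  expect_equal(old, round(-0.635 * r^(0:4), 4))
  # gradients: |value| decreasing with quintile, young at least old
  for (g in c("15-24", "25+")) {
    v <- vapply(1:5, function(q) cell(g, q), numeric(1))
    expect_true(all(diff(abs(v)) < 0))
  }
  for (q in 1:5) expect_gte(abs(cell("15-24", q)), abs(cell("25+", q)))
  expect_error(build_elasticity_matrix(anchor_young_bottom = 0.5), "negative")
  expect_error(build_elasticity_matrix(age_ratio = -1), "age_ratio")
})

test_that("effective elasticity maps bands to age groups", {
  m <- build_elasticity_matrix()
  expect_equal(effective_elasticity(m, "20-24", 1), -1.27)
  expect_equal(effective_elasticity(m, "60-64", 5), -0.24)
  expect_equal(effective_elasticity(m, "future", 1), -1.27)
  u <- uniform_elasticity_matrix(-0.4)
  expect_equal(effective_elasticity(u, c("15-19", "45-49", "85-89"), c(1, 3, 5)),
               rep(-0.4, 3))
  expect_error(effective_elasticity(m, "12-14", 1), "age band")
})

test_that("arc response splits into quitting and intensity reduction", {
  # the headline anchor: -0.4 elasticity, +50% price, half the 20% fall quits
  expect_equal(quit_fraction(-0.4, 0.5, 0.5), 0.10)
  expect_equal(quit_fraction(-0.4, 0.5, 1.0), 0.20)
  expect_equal(intensity_reduction(-0.4, 0.5, 0.5), 0.10)
  expect_equal(intensity_reduction(-0.24, 0.5, 0.5), 0.06)
  expect_equal(quit_fraction(-4.0, 1.0, 0.5), 1.0)  # capped
  expect_equal(intensity_reduction(-0.4, 0, 0.5), 0)
})

test_that("stratum quitters scale with smokers and never exceed them", {
  p <- test_profiles(quintile_smokers = list(rep(2, 5)))
  strata <- synthesize_age_structure(p, seed = 3)
  scen <- scenario(price_increase = 0.5, seed = 3)
  out <- quitters_by_stratum(strata, uniform_elasticity_matrix(-0.4), scen)
  expect_equal(sum(out$quitters), 0.10 * sum(out$smokers))
  expect_true(all(out$quitters <= out$smokers))
  # single stratum check: 2.0M smokers at -1.27 and +50% price
  one <- tibble::tibble(country = "X", age_band = "20-24", quintile = 1,
                        smokers = 2, sticks_per_day = 10)
  got <- quitters_by_stratum(one, build_elasticity_matrix(), scen)
  expect_equal(got$quitters, 2 * min(1, 1.27 * 0.5 * 0.5))
  # monotone in the price increase and in |elasticity|
  q1 <- quitters_by_stratum(strata, uniform_elasticity_matrix(-0.4),
                            scenario(price_increase = 0.25))
  q2 <- quitters_by_stratum(strata, uniform_elasticity_matrix(-0.4),
                            scenario(price_increase = 1.0))
  expect_true(all(q2$quitters >= q1$quitters))
  q3 <- quitters_by_stratum(strata, uniform_elasticity_matrix(-0.6),
                            scenario(price_increase = 0.25))
  expect_true(all(q3$quitters >= q1$quitters))
})

test_that("the smoker-weighted mean of the anchored matrix is near -0.4", {
  p <- load_country_profiles()
  strata <- synthesize_age_structure(p, seed = 5)
  m <- mean_realized_elasticity(strata, build_elasticity_matrix())
  expect_gt(m, -0.6)
  expect_lt(m, -0.2)
})

test_that("matrix CSV round trip and country rescaling", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- build_elasticity_matrix()
  readr::write_csv(tibble::as_tibble(m), path)
  m2 <- read_elasticity_matrix(path)
  expect_equal(m2$elasticity, m$elasticity)
  sc <- scale_elasticity_matrix(m, -0.8)
  expect_equal(sc$elasticity, m$elasticity * 2)
})
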