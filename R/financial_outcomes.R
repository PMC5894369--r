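#' Lognormal income model from a Gini coefficient
#'
#' For a lognormal income distribution the Gini coefficient depends only on
#' the log-scale parameter: `G = 2 * pnorm(sigma / sqrt(2)) - 1`. Inverting
#' gives `sigma = sqrt(2) * qnorm((G + 1) / 2)`, and matching the mean gives
#' `mu = log(mean_income) - sigma^2 / 2`. A Gini of 0 yields the degenerate
#' distribution with all mass at the mean.
#'
#' @param gini Gini coefficient in \[0, 1).
#' @param mean_income Mean per-capita income, $PPP/year (> 0).
#' @return A list with elements `mu`, `sigma`, `mean_income`, `gini`, of
#'   class `"smoketax_income_model"`.
#' @export
#' @examples
#' m <- lognormal_from_gini(0.46, 10000)
#' gini_lognormal(m$sigma)  # recovers 0.46
lognormal_from_gini <- function(gini, mean_income) {
  if (gini < 0 || gini >= 1) abort("gini must be in [0, 1)")
  if (mean_income <= 0) abort("mean_income must be > 0")
  sigma <- sqrt(2) * qnorm((gini + 1) / 2)
  structure(
    list(mu = log(mean_income) - sigma^2 / 2, sigma = sigma,
         mean_income = mean_income, gini = gini),
    class = "smoketax_income_model"
  )
}

#' @rdname lognormal_from_gini
#' @param sigma Lognormal log-scale parameter.
#' @export
gini_lognormal <- function(sigma) {
  2 * pnorm(sigma / sqrt(2)) - 1
}

# Quantile function of the income model (degenerate-safe).
income_quantile <- function(model, p) {
  if (model$sigma == 0) rep(model$mean_income, length(p))
  else qlnorm(p, model$mu, model$sigma)
}

# CDF of the income model (degenerate-safe).
income_cdf <- function(model, x) {
  if (model$sigma == 0) as.numeric(x >= model$mean_income)
  else plnorm(x, model$mu, model$sigma)
}

# P(income <= x | income in quintile q's quantile interval).
quintile_prob_below <- function(model, quintile, x) {
  lo <- (quintile - 1) / 5
  hi <- quintile / 5
  if (model$sigma == 0) {
    # point mass at the mean sits in every quintile interval
    return(as.numeric(x >= model$mean_income))
  }
  p <- income_cdf(model, x)
  (pmin(pmax(p, lo), hi) - lo) / (hi - lo)
}

#' Out-of-pocket share of treatment costs
#'
#' The share of a disease's treatment cost paid out of pocket is
#' `1 - coverage_fraction * public_cost_share`, evaluated per country,
#' quintile and disease after applying any coverage overrides (for schemes
#' that cover only certain diseases or quintiles, such as Mexico's Seguro
#' Popular).
#'
#' @param profiles A profile tibble from [load_country_profiles()].
#' @param overrides An override tibble from [load_coverage_overrides()], or
#'   `NULL` for none. The packaged Mexico override is NOT applied unless
#'   passed explicitly.
#' @return A tibble `country`, `quintile`, `disease`, `oop_share` covering
#'   every (country, quintile, disease) cell.
#' @export
#' @examples
#' os <- oop_share(load_country_profiles())
#' dplyr::filter(os, country == "India", quintile == 1)
oop_share <- function(profiles, overrides = NULL) {
  base <- profiles |>
    as_tibble() |>
    select("country", "coverage_fraction", "public_cost_share", "diseases") |>
    mutate(disease = purrr::map(.data$diseases, "disease")) |>
    select(-"diseases") |>
    tidyr::unnest_longer("disease") |>
    tidyr::expand_grid(quintile = 1:5)
  if (!is.null(overrides) && nrow(overrides) > 0) {
    base <- base |>
      left_join(overrides, by = c("country", "quintile", "disease"),
                suffix = c("", ".ovr")) |>
      mutate(
        coverage_fraction = coalesce(.data$coverage_fraction.ovr, .data$coverage_fraction),
        public_cost_share = coalesce(.data$public_cost_share.ovr, .data$public_cost_share)
      ) |>
      select(-dplyr::ends_with(".ovr"))
  }
  base |>
    transmute(.data$country, .data$quintile, .data$disease,
              oop_share = pmin(1, pmax(0, 1 - .data$coverage_fraction * .data$public_cost_share)))
}

#' Treatment costs averted
#'
#' Total cost averted is the sum over diseases of averted fatal cases times
#' the lifetime treatment cost per case; the out-of-pocket part weights each
#' disease term by its out-of-pocket share.
#'
#' @param deaths_by_disease A tibble with columns `country`, `quintile`,
#'   `disease` and `disease_deaths` (from [apportion_deaths()], any extra
#'   stratum columns preserved in the grouping).
#' @param unit_costs A tibble `country`, `disease`, `unit_cost` ($PPP per
#'   fatal case, >= 0).
#' @param oop_shares A tibble from [oop_share()].
#' @param by Grouping columns for the output (default country and quintile).
#' @return A tibble with `cost_averted_total` and `cost_averted_oop` ($PPP)
#'   per group.
#' @export
costs_averted <- function(deaths_by_disease, unit_costs, oop_shares,
                          by = c("country", "quintile")) {
  if (any(unit_costs$unit_cost < 0)) abort("unit costs must be >= 0")
  deaths_by_disease |>
    left_join(unit_costs, by = c("country", "disease")) |>
    left_join(oop_shares, by = c("country", "quintile", "disease")) |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(
      cost_averted_total = sum(.data$disease_deaths * .data$unit_cost),
      cost_averted_oop = sum(.data$disease_deaths * .data$unit_cost * .data$oop_share),
      .groups = "drop"
    )
}

#' Men avoiding catastrophic health expenditure
#'
#' A treated case incurs catastrophic health expenditure when its
#' out-of-pocket cost exceeds 10% of the individual's annual income (the WHO
#' definition). The probability is evaluated in closed form under the
#' country's lognormal income model truncated to the quintile's
#' population-quantile interval, and multiplied by the number of averted
#' cases.
#'
#' @param cases Averted treated cases (millions), vectorised.
#' @param oop_cost_per_case Out-of-pocket cost per case, $PPP (>= 0).
#' @param income_model A model from [lognormal_from_gini()].
#' @param quintile Quintile index 1..5 (recycled with `cases`).
#' @param threshold Catastrophic threshold as a fraction of annual income
#'   (default 0.1).
#' @return Men avoiding catastrophic expenditure (millions).
#' @export
catastrophic_averted <- function(cases, oop_cost_per_case, income_model,
                                 quintile, threshold = 0.1) {
  if (any(oop_cost_per_case < 0)) abort("oop_cost_per_case must be >= 0")
  n <- max(length(cases), length(quintile), length(oop_cost_per_case))
  cases <- rep_len(cases, n)
  quintile <- rep_len(quintile, n)
  cost <- rep_len(oop_cost_per_case, n)
  p <- vapply(seq_len(n), function(i) {
    if (cost[i] == 0) return(0)
    quintile_prob_below(income_model, quintile[i], cost[i] / threshold)
  }, numeric(1))
  cases * p
}

#' Men avoiding falling into extreme poverty
#'
#' A treated case is impoverishing when the individual's income is at or
#' above the extreme-poverty line but falls below it once the out-of-pocket
#' cost is paid (the World Bank $1.90/day definition, annualised over 365
#' days). The probability is the mass of the truncated income distribution
#' in `[L, L + cost)`.
#'
#' @inheritParams catastrophic_averted
#' @param poverty_line_per_day Poverty line, $PPP/day (default 1.90).
#' @param days Days per year used to annualise the line (default 365).
#' @return Men avoiding extreme poverty (millions).
#' @export
poverty_averted <- function(cases, oop_cost_per_case, income_model, quintile,
                            poverty_line_per_day = 1.90, days = 365) {
  if (any(oop_cost_per_case < 0)) abort("oop_cost_per_case must be >= 0")
  line <- poverty_line_per_day * days
  n <- max(length(cases), length(quintile), length(oop_cost_per_case))
  cases <- rep_len(cases, n)
  quintile <- rep_len(quintile, n)
  cost <- rep_len(oop_cost_per_case, n)
  p <- vapply(seq_len(n), function(i) {
    if (cost[i] == 0) return(0)
    quintile_prob_below(income_model, quintile[i], line + cost[i]) -
      quintile_prob_below(income_model, quintile[i], line)
  }, numeric(1))
  cases * pmax(p, 0)
}

#' Excise increase needed for a given price rise
#'
#' Under full pass-through the retail price rises by exactly the excise
#' increase, so a fractional price rise of `price_increase` needs an excise
#' increase of `price_increase * price_per_pack` $PPP per pack.
#'
#' @param price_per_pack Retail price per 20-stick pack, $PPP.
#' @param price_increase Fractional price increase.
#' @return Excise increase per pack, $PPP.
#' @export
#' @examples
#' excise_increase_for_price_rise(9.2, 0.5)  # 4.6
excise_increase_for_price_rise <- function(price_per_pack, price_increase) {
  if (any(price_increase < 0)) abort("price_increase must be >= 0")
  price_increase * price_per_pack
}

#' Percentage increase in the excise rate
#'
#' Expresses the needed excise increase relative to the baseline excise,
#' taking the baseline excise to be `excise_fraction_of_tax` of the total tax
#' share of the retail price (default one half, which reproduces the
#' published rate increases for all 13 countries):
#' `100 * price_increase / (excise_fraction_of_tax * tax_share)`, rounded to
#' the nearest integer.
#'
#' @param price_per_pack Retail price per pack, $PPP (enters the numerator
#'   and denominator and cancels; kept for interface clarity).
#' @param tax_share Tax share of the retail price, in (0, 1].
#' @param price_increase Fractional price increase.
#' @param excise_fraction_of_tax Baseline excise as a fraction of total tax
#'   (default 0.5).
#' @return Percent increase in the excise rate (integer-rounded).
#' @export
#' @examples
#' excise_rate_increase_pct(2.8, 0.508, 0.5)  # 197 (China)
excise_rate_increase_pct <- function(price_per_pack, tax_share, price_increase,
                                     excise_fraction_of_tax = 0.5) {
  if (any(tax_share <= 0)) abort("tax_share must be > 0")
  round(100 * (price_increase * price_per_pack) /
          (excise_fraction_of_tax * tax_share * price_per_pack))
}

#' Additional excise revenue per stratum
#'
#' Revenue before the rise is smokers x packs/year x tax per pack (tax share
#' times price). After the rise, continuing smokers (those who do not quit)
#' smoke fewer packs (the intensity response) and pay the old tax plus the
#' full excise increase on each pack. The difference is the additional
#' revenue. For elasticities of magnitude at most 1 and price rises up to
#' 100% this is always positive: the higher tax per pack dominates the
#' demand loss.
#'
#' @param smokers Smokers in the stratum (millions), vectorised.
#' @param sticks_per_day Mean cigarettes/day.
#' @param price_per_pack Retail price per 20-stick pack, $PPP.
#' @param tax_share Tax share of retail price.
#' @param elasticity Stratum price elasticity (<= 0).
#' @param price_increase Fractional price increase.
#' @param quit_share Share of the response due to quitting.
#' @return Additional revenue in millions of $PPP per year (when smokers are
#'   in millions).
#' @export
#' @examples
#' extra_tax_revenue(1, 10, 4, 0.5, -0.4, 0.5)  # ~226.3 ($m per 1M smokers)
extra_tax_revenue <- function(smokers, sticks_per_day, price_per_pack,
                              tax_share, elasticity, price_increase,
                              quit_share = 0.5) {
  packs_per_year <- sticks_per_day * 365 / 20
  before <- smokers * packs_per_year * tax_share * price_per_pack
  qf <- quit_fraction(elasticity, price_increase, quit_share)
  ir <- intensity_reduction(elasticity, price_increase, quit_share)
  tax_after <- tax_share * price_per_pack + price_increase * price_per_pack
  after <- smokers * (1 - qf) * packs_per_year * (1 - ir) * tax_after
  after - before
}
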