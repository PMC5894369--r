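#' Build the anchored age-by-quintile elasticity matrix
#'
#' Price responsiveness of cigarette demand is roughly twice as great in
#' young smokers (ages 15-24) and in smokers on low incomes as in older,
#' richer smokers. The default matrix pins the two published anchor cells —
#' -1.27 for young smokers in the poorest quintile and -0.24 for smokers aged
#' 25+ in the richest — and interpolates geometrically in between: the 25+
#' row runs from `anchor_young_bottom / age_ratio` at quintile 1 to
#' `anchor_old_top` at quintile 5 with a constant ratio per quintile step,
#' and the young row is `age_ratio` times the 25+ row with its bottom cell
#' pinned exactly to `anchor_young_bottom`. Entries are reported to 4
#' decimals.
#'
#' @param anchor_young_bottom Elasticity for ages 15-24, poorest quintile
#'   (default -1.27). Must be negative.
#' @param anchor_old_top Elasticity for ages 25+, richest quintile
#'   (default -0.24). Must be negative.
#' @param age_ratio Young : old responsiveness ratio (default 2).
#' @param n_quintiles Number of income quintiles (default 5).
#' @return A tibble with columns `age_group` (`"15-24"` / `"25+"`),
#'   `quintile` and `elasticity`, carrying attribute `mean_target` (-0.4, the
#'   consensus average elasticity the matrix is centred on) and class
#'   `"smoketax_elasticity"`.
#' @export
#' @examples
#' build_elasticity_matrix()
build_elasticity_matrix <- function(anchor_young_bottom = -1.27,
                                    anchor_old_top = -0.24,
                                    age_ratio = 2,
                                    n_quintiles = 5) {
  if (anchor_young_bottom >= 0 || anchor_old_top >= 0) {
    abort("elasticity anchors must be negative")
  }
  if (age_ratio <= 0) abort("age_ratio must be > 0")
  old_bottom <- anchor_young_bottom / age_ratio
  r <- (anchor_old_top / old_bottom)^(1 / (n_quintiles - 1))
  old <- old_bottom * r^(seq_len(n_quintiles) - 1)
  young <- age_ratio * old
  young[1] <- anchor_young_bottom
  out <- tibble(
    age_group = rep(c("15-24", "25+"), each = n_quintiles),
    quintile = rep(seq_len(n_quintiles), 2),
    elasticity = round(c(young, old), 4)
  )
  attr(out, "mean_target") <- -0.4
  class(out) <- c("smoketax_elasticity", class(out))
  out
}

#' Uniform elasticity matrix
#'
#' A flat matrix with the same elasticity in every age group and quintile;
#' the default -0.4 is the consensus average used as the headline demand
#' response.
#'
#' @param value Elasticity (negative; default -0.4).
#' @inheritParams build_elasticity_matrix
#' @return Same structure as [build_elasticity_matrix()].
#' @export
uniform_elasticity_matrix <- function(value = -0.4, n_quintiles = 5) {
  if (value > 0) abort("elasticity must be <= 0")
  out <- tibble(
    age_group = rep(c("15-24", "25+"), each = n_quintiles),
    quintile = rep(seq_len(n_quintiles), 2),
    elasticity = value
  )
  attr(out, "mean_target") <- value
  class(out) <- c("smoketax_elasticity", class(out))
  out
}

#' Read an elasticity matrix from CSV
#'
#' Accepts a user-supplied matrix with columns `age_group` (`"15-24"`,
#' `"25+"`), `quintile` and `elasticity`, replacing the anchored default.
#'
#' @param path CSV path.
#' @return An elasticity matrix tibble.
#' @export
read_elasticity_matrix <- function(path) {
  df <- read_table_checked(path, "elasticity matrix")
  require_columns(df, c("age_group", "quintile", "elasticity"), "elasticity matrix")
  out <- df |>
    mutate(quintile = as.integer(.data$quintile),
           elasticity = as.numeric(.data$elasticity))
  if (any(out$elasticity > 0)) abort("elasticities must be <= 0")
  attr(out, "mean_target") <- -0.4
  class(out) <- c("smoketax_elasticity", class(out))
  out
}

#' Rescale an elasticity matrix to a country-specific mean
#'
#' For the country-specific sensitivity analysis every cell is multiplied by
#' `country_elasticity / mean_target`, preserving the age and income gradient
#' while moving the overall level.
#'
#' @param matrix An elasticity matrix tibble.
#' @param country_elasticity The country's overall elasticity (negative).
#' @return A rescaled elasticity matrix.
#' @export
scale_elasticity_matrix <- function(matrix, country_elasticity) {
  target <- attr(matrix, "mean_target") %||% -0.4
  out <- matrix |> mutate(elasticity = .data$elasticity * country_elasticity / target)
  attr(out, "mean_target") <- country_elasticity
  class(out) <- unique(c("smoketax_elasticity", class(out)))
  out
}

#' Look up the elasticity for an age band and quintile
#'
#' Age bands 15-19 and 20-24 (and the under-15 future cohort, labelled
#' `"future"`) map to the young group; all other bands map to 25+.
#'
#' @param matrix An elasticity matrix tibble.
#' @param age_band Character vector of band labels from [age_bands()], or
#'   `"future"`.
#' @param quintile Integer vector of quintiles (recycled with `age_band`).
#' @return Numeric elasticities.
#' @export
#' @examples
#' effective_elasticity(build_elasticity_matrix(), "20-24", 1)
effective_elasticity <- function(matrix, age_band, quintile) {
  known <- c(age_bands()$age_band, "future")
  bad <- setdiff(unique(age_band), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown age band(s): %s", paste(bad, collapse = ", ")))
  }
  group <- ifelse(age_band %in% c("15-19", "20-24", "future"), "15-24", "25+")
  key <- paste(group, quintile)
  lut <- stats::setNames(matrix$elasticity, paste(matrix$age_group, matrix$quintile))
  out <- unname(lut[key])
  if (anyNA(out)) abort("quintile outside the matrix range")
  out
}

#' Fraction of smokers who quit after a price rise
#'
#' The demand response is applied as an arc approximation: the fractional
#' fall in consumption is `|elasticity| * price_increase`, of which
#' `quit_share` is attributed to complete cessation (the remainder to fewer
#' cigarettes per day). Capped at 1.
#'
#' @param elasticity Price elasticity (<= 0), vectorised.
#' @param price_increase Fractional retail price increase (e.g. 0.5 for
#'   +50%).
#' @param quit_share Share of the consumption response due to quitting
#'   (default 0.5).
#' @return Fraction of smokers quitting, in \[0, 1\].
#' @export
#' @examples
#' quit_fraction(-0.4, 0.5)  # 0.10: the headline 10% cessation response
quit_fraction <- function(elasticity, price_increase, quit_share = 0.5) {
  if (any(price_increase < 0)) abort("price_increase must be >= 0")
  if (any(quit_share < 0 | quit_share > 1)) abort("quit_share must be in [0, 1]")
  pmin(1, abs(elasticity) * price_increase * quit_share)
}

#' Fractional reduction in daily cigarettes among continuing smokers
#'
#' The complement of [quit_fraction()]: the `1 - quit_share` part of the arc
#' consumption response, expressed as the fractional fall in sticks/day of
#' those who keep smoking. Capped at 1.
#'
#' @inheritParams quit_fraction
#' @return Fractional intensity reduction in \[0, 1\].
#' @export
intensity_reduction <- function(elasticity, price_increase, quit_share = 0.5) {
  if (any(price_increase < 0)) abort("price_increase must be >= 0")
  if (any(quit_share < 0 | quit_share > 1)) abort("quit_share must be in [0, 1]")
  pmin(1, abs(elasticity) * price_increase * (1 - quit_share))
}

#' Quitters per population stratum
#'
#' Applies the stratum's effective elasticity to the scenario's price
#' increase and appends `elasticity`, `quit_frac` and `quitters` columns.
#' Quitters never exceed the stratum's smokers.
#'
#' @param strata A stratum tibble from [synthesize_age_structure()].
#' @param matrix An elasticity matrix tibble.
#' @param scenario A [scenario()] object (its `price_increase` and
#'   `quit_share` are used).
#' @return The stratum tibble with response columns appended.
#' @export
quitters_by_stratum <- function(strata, matrix, scenario) {
  strata |>
    mutate(
      elasticity = effective_elasticity(matrix, .data$age_band, .data$quintile),
      quit_frac = quit_fraction(.data$elasticity, scenario$price_increase,
                                scenario$quit_share),
      quitters = .data$smokers * .data$quit_frac
    )
}

#' Smoker-weighted mean elasticity
#'
#' Reports the realised average elasticity of a matrix over a stratum table,
#' for checking consistency with the consensus mean of about -0.4.
#'
#' @param strata A stratum tibble.
#' @param matrix An elasticity matrix tibble.
#' @return A single number.
#' @export
mean_realized_elasticity <- function(strata, matrix) {
  e <- effective_elasticity(matrix, strata$age_band, strata$quintile)
  sum(e * strata$smokers) / sum(strata$smokers)
}

#' Define a price-increase scenario
#'
#' Bundles the policy lever (the fractional retail price increase), the
#' behavioural assumptions (quit share, elasticity specification), the
#' inclusion sets for sensitivity analyses, and the seed for the synthetic
#' age structure.
#'
#' @param price_increase Fractional one-time retail price increase
#'   (default 0.5; the sensitivity suite uses 0.25 and 1.0).
#' @param quit_share Share of the consumption response due to quitting
#'   (default 0.5).
#' @param elasticity Either an elasticity matrix tibble (default the anchored
#'   matrix of [build_elasticity_matrix()]), or a named numeric vector of
#'   per-country overall elasticities, in which case the anchored matrix is
#'   rescaled per country via [scale_elasticity_matrix()].
#' @param include_countries Character vector of countries to run, or `NULL`
#'   for all.
#' @param include_female If `TRUE`, inflate smokers in the countries of
#'   `female_shares` so that totals include female smokers.
#' @param female_shares Named fractions of total smokers who are female, used
#'   only when `include_female = TRUE`. Defaults: Chile 46%, Colombia 29%,
#'   Mexico 29%.
#' @param initiation_fraction Future-smoker cohort control; see
#'   [synthesize_future_cohort()]. Default 0 (off).
#' @param case_multiplier Treated cases per averted fatal case used in the
#'   financial-risk computations (default 1: fatal cases only).
#' @param poverty_line_per_day Extreme-poverty line, $PPP/day (default 1.90).
#' @param jitter Dirichlet jitter for the synthetic age structure (default 0).
#' @param seed Integer seed.
#' @return A list with class `"smoketax_scenario"`.
#' @export
#' @examples
#' scenario(price_increase = 0.5)
scenario <- function(price_increase = 0.5,
                     quit_share = 0.5,
                     elasticity = build_elasticity_matrix(),
                     include_countries = NULL,
                     include_female = FALSE,
                     female_shares = c(Chile = 0.46, Colombia = 0.29, Mexico = 0.29),
                     initiation_fraction = 0,
                     case_multiplier = 1,
                     poverty_line_per_day = 1.90,
                     jitter = 0,
                     seed = 1L) {
  if (price_increase <= 0) abort("price_increase must be > 0")
  if (quit_share < 0 || quit_share > 1) abort("quit_share must be in [0, 1]")
  structure(
    list(
      price_increase = price_increase,
      quit_share = quit_share,
      elasticity = elasticity,
      include_countries = include_countries,
      include_female = include_female,
      female_shares = female_shares,
      initiation_fraction = initiation_fraction,
      case_multiplier = case_multiplier,
      poverty_line_per_day = poverty_line_per_day,
      jitter = jitter,
      seed = as.integer(seed)
    ),
    class = "smoketax_scenario"
  )
}
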