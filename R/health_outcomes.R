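#' Fit the life-years-gained-by-cessation schedule
#'
#' Cohort studies of cessation report the life expectancy regained by the age
#' at which a smoker quits: about 10 years for quitting before 30, and 9, 6
#' and 3 years for quitting at 30-44, 45-64 and 65+ respectively. The
#' schedule smooths these interval estimates onto the model's 5-year age
#' grid with a monotone shape-preserving cubic interpolant (Fritsch-Carlson)
#' through the interval midpoints (22.5, 10), (37.5, 9), (55, 6), (75, 3),
#' extended as a constant below 22.5 and above 75, so the grid is guaranteed
#' non-increasing in age.
#'
#' @param knots A tibble/data.frame with columns `age` (interval midpoint of
#'   the cessation-age class) and `years_gained`, strictly decreasing in
#'   `years_gained` with age. The default encodes the published 10/9/6/3
#'   schedule.
#' @return A tibble `age_band`, `life_years_per_quitter` with class
#'   `"smoketax_schedule"`.
#' @export
#' @examples
#' fit_life_year_schedule()
fit_life_year_schedule <- function(knots = default_life_year_knots()) {
  require_columns(knots, c("age", "years_gained"), "life-year knots")
  if (is.unsorted(knots$age, strictly = TRUE)) abort("knot ages must be increasing")
  if (any(diff(knots$years_gained) >= 0)) {
    abort("years gained must be strictly decreasing with cessation age")
  }
  f <- splinefun(knots$age, knots$years_gained, method = "monoH.FC")
  bands <- age_bands()
  x <- pmin(pmax(bands$mid, min(knots$age)), max(knots$age))
  out <- tibble(
    age_band = bands$age_band,
    life_years_per_quitter = f(x)
  )
  class(out) <- c("smoketax_schedule", class(out))
  out
}

#' @rdname fit_life_year_schedule
#' @export
default_life_year_knots <- function() {
  tibble(age = c(22.5, 37.5, 55, 75), years_gained = c(10, 9, 6, 3))
}

#' Life years gained from quitting, by stratum
#'
#' Each quitter gains the schedule value for their age band; the same
#' schedule is applied in every income quintile, and no benefit is credited
#' for reduced smoking intensity (a deliberately conservative choice).
#'
#' @param quitters A stratum tibble with `age_band` and `quitters` columns
#'   (from [quitters_by_stratum()]).
#' @param schedule A schedule from [fit_life_year_schedule()].
#' @return The input with a `life_years` column appended (millions of years
#'   when quitters are in millions).
#' @export
life_years_gained <- function(quitters, schedule = fit_life_year_schedule()) {
  quitters |>
    left_join(as_tibble(schedule), by = "age_band") |>
    mutate(life_years = .data$quitters * .data$life_years_per_quitter) |>
    select(-"life_years_per_quitter")
}

#' Smoking-attributable deaths averted, by stratum
#'
#' At least half of persistent smokers who start in early adult life are
#' killed by their habit, losing on average 10 years. Deaths averted per
#' quitter are anchored at `death_risk` for the youngest quitters (who regain
#' the full 10 years) and scaled down with age in proportion to the life-year
#' schedule, so the per-quitter benefit decays like the years regained.
#'
#' @param quitters A stratum tibble with `age_band` and `quitters` columns.
#' @param schedule A schedule from [fit_life_year_schedule()].
#' @param death_risk Probability that a continuing smoker eventually dies of
#'   smoking (default 0.5).
#' @return The input with a `deaths_averted` column appended.
#' @export
deaths_averted <- function(quitters, schedule = fit_life_year_schedule(),
                           death_risk = 0.5) {
  if (death_risk < 0 || death_risk > 1) abort("death_risk must be in [0, 1]")
  sched <- as_tibble(schedule)
  top <- max(sched$life_years_per_quitter)
  quitters |>
    left_join(sched, by = "age_band") |>
    mutate(deaths_averted = .data$quitters * death_risk *
             .data$life_years_per_quitter / top) |>
    select(-"life_years_per_quitter")
}

#' Apportion averted deaths across the four disease groups
#'
#' Smoking-attributable mortality is split across chronic obstructive
#' pulmonary disease, stroke, heart disease and cancers (tuberculosis is
#' ignored) by fixed country shares summing to one, so disease-level deaths
#' sum back to the stratum total exactly.
#'
#' @param deaths A tibble with a `deaths_averted` column and a `country`
#'   column.
#' @param disease_mix A tibble `country`, `disease`, `mix_share` (shares sum
#'   to 1 within country).
#' @return One row per (stratum, disease), with `disease_deaths` appended.
#' @export
apportion_deaths <- function(deaths, disease_mix) {
  require_columns(disease_mix, c("country", "disease", "mix_share"), "disease mix")
  chk <- disease_mix |>
    group_by(.data$country) |>
    summarise(s = sum(.data$mix_share), .groups = "drop")
  if (any(abs(chk$s - 1) > 1e-9)) {
    abort(sprintf("disease mix does not sum to 1 for: %s",
                  paste(chk$country[abs(chk$s - 1) > 1e-9], collapse = ", ")))
  }
  deaths |>
    left_join(disease_mix, by = "country", relationship = "many-to-many") |>
    mutate(disease_deaths = .data$deaths_averted * .data$mix_share)
}
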