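#' Synthesize the age structure of smokers
#'
#' The model needs smokers resolved by 5-year age band within each income
#' quintile, but only quintile totals are published. This generator allocates
#' each (country, quintile) total across the bands of [age_bands()] in
#' proportion to a non-negative weight curve, optionally perturbed by
#' Dirichlet jitter, conserving the quintile totals exactly. It stands in for
#' the survey-derived age-by-quintile prevalence tables that are not
#' published, and is deterministic given the seed (per-country substreams are
#' derived by hashing the country name, so results do not depend on country
#' order).
#'
#' The default weight curve is triangular: rising to a peak at ages 35-39 and
#' falling to zero above age 84, a stylised shape for adult male smoking in
#' middle income countries.
#'
#' @param profiles A profile tibble from [load_country_profiles()].
#' @param weights Either the string `"triangular"` (default), `"uniform"`, or
#'   a numeric vector of 15 non-negative band weights (ages 15-19 ... 85-89).
#' @param jitter Dirichlet jitter scale; 0 (default) allocates exactly
#'   proportionally to the weights, larger values add more stratum-level
#'   noise while still conserving quintile totals.
#' @param seed Integer seed.
#' @return A tibble of population strata: `country`, `age_band`, `quintile`,
#'   `smokers` (millions) and `sticks_per_day` (the country mean; the
#'   published tables give no per-stratum breakdown).
#' @export
#' @examples
#' strata <- synthesize_age_structure(load_country_profiles(), seed = 1)
#' dplyr::count(strata, country, wt = smokers)
synthesize_age_structure <- function(profiles, weights = "triangular",
                                     jitter = 0, seed = 1L) {
  bands <- age_bands()
  w <- band_weights(weights, bands)
  if (all(w <= 0)) abort("age-band weights are all zero")
  if (jitter < 0) abort("jitter must be >= 0")

  one_country <- function(p) {
    q_tot <- p$smokers_by_quintile[[1]]
    cs <- country_seed(seed, p$country)
    alloc <- with_seed(cs, {
      lapply(seq_along(q_tot), function(q) {
        wq <- w / sum(w)
        if (jitter > 0) {
          g <- ifelse(wq > 0, rgamma(length(wq), shape = wq / jitter, rate = 1), 0)
          # guard against all-zero gamma draws at extreme jitter
          wq <- if (sum(g) > 0) g / sum(g) else wq
        }
        q_tot[q] * wq / sum(wq)
      })
    })
    tidyr::expand_grid(age_band = bands$age_band, quintile = seq_along(q_tot)) |>
      arrange(.data$quintile) |>
      mutate(country = p$country,
             smokers = unlist(alloc),
             sticks_per_day = p$sticks_per_day)
  }

  pt <- as_tibble(profiles)
  purrr::map(seq_len(nrow(pt)), function(i) one_country(pt[i, ])) |>
    purrr::list_rbind() |>
    select("country", "age_band", "quintile", "smokers", "sticks_per_day")
}

band_weights <- function(weights, bands) {
  if (is.character(weights)) {
    switch(weights,
      triangular = {
        peak <- 37.5; left <- 10; right <- 85
        pmax(0, ifelse(bands$mid <= peak,
                       (bands$mid - left) / (peak - left),
                       (right - bands$mid) / (right - peak)))
      },
      uniform = rep(1, nrow(bands)),
      abort(sprintf("unknown weight preset '%s'", weights))
    )
  } else {
    w <- as.numeric(weights)
    if (length(w) != nrow(bands)) {
      abort(sprintf("need %d band weights, got %d", nrow(bands), length(w)))
    }
    if (any(w < 0)) abort("band weights must be >= 0")
    w
  }
}

#' Synthesize a future-smoker cohort
#'
#' Children below 15 who would have initiated smoking absent the price rise.
#' The published analysis applies the youngest-age elasticity to this cohort
#' but does not quantify its size, so the default `initiation_fraction` of 0
#' switches it off. When on, the cohort is distributed across quintiles in
#' proportion to current smokers.
#'
#' @param profiles A profile tibble.
#' @param initiation_fraction Fraction in \[0, 1\] of the cohort that would
#'   initiate; 0 disables the cohort.
#' @param cohort_size_m Cohort size per country, millions; default the
#'   country's current smoker total (so `initiation_fraction = 1` reproduces
#'   the current quintile distribution). Either a single number or a vector
#'   named by country.
#' @param seed Integer seed (the allocation is deterministic; the seed is
#'   accepted for interface symmetry with the other generators).
#' @return A tibble `country`, `quintile`, `future_smokers` (millions).
#' @export
synthesize_future_cohort <- function(profiles, initiation_fraction = 0,
                                     cohort_size_m = NULL, seed = 1L) {
  if (initiation_fraction < 0 || initiation_fraction > 1) {
    abort("initiation_fraction must be in [0, 1]")
  }
  profiles |>
    as_tibble() |>
    transmute(
      country = .data$country,
      shares = purrr::map(.data$smokers_by_quintile, ~ .x / sum(.x)),
      total = purrr::map_dbl(.data$smokers_by_quintile, sum)
    ) |>
    mutate(cohort = if (is.null(cohort_size_m)) .data$total
           else if (length(cohort_size_m) == 1) cohort_size_m
           else unname(cohort_size_m[.data$country])) |>
    tidyr::unnest_longer("shares", values_to = "share", indices_to = "quintile") |>
    transmute(.data$country, quintile = as.integer(.data$quintile),
              future_smokers = initiation_fraction * .data$cohort * .data$share)
}

#' Sample incomes within one quintile
#'
#' Draws individual annual incomes from the country's Gini-parameterised
#' lognormal income distribution, truncated to the population-quantile
#' interval of the requested quintile (`[(q-1)/5, q/5]`). Used as the
#' Monte-Carlo oracle for the closed-form catastrophic-expenditure and
#' impoverishment probabilities.
#'
#' @param profile A single-row profile tibble (one country).
#' @param quintile Quintile index, 1 (poorest) to 5 (richest).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A numeric vector of `n` incomes in $PPP/year.
#' @export
#' @examples
#' p <- dplyr::filter(load_country_profiles(), country == "India")
#' mean(sample_quintile_incomes(p, 1, 1000, seed = 1))
sample_quintile_incomes <- function(profile, quintile, n, seed = 1L) {
  if (nrow(profile) != 1) abort("profile must be a single country row")
  if (!quintile %in% 1:5) abort("quintile must be an integer in 1..5")
  if (n < 1) abort("n must be >= 1")
  model <- lognormal_from_gini(profile$gini, profile$mean_income)
  with_seed(seed, {
    u <- runif(n, (quintile - 1) / 5, quintile / 5)
    income_quantile(model, u)
  })
}
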