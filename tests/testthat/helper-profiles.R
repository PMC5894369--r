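# A minimal valid in-code profile table for unit tests (one or two synthetic
# countries), shaped exactly like load_country_profiles() output.
test_profiles <- function(countries = "Testland",
                          gini = 0.4,
                          mean_income = 8000,
                          quintile_smokers = list(c(2, 2, 2, 2, 2)),
                          sticks_per_day = 10,
                          price_per_pack = 4,
                          tax_share = 0.5,
                          coverage_fraction = 0.5,
                          public_cost_share = 0.5,
                          frp_subset = TRUE) {
  n <- length(countries)
  diseases <- lapply(seq_len(n), function(i) {
    tibble::tibble(
      disease = c("copd", "stroke", "heart_disease", "cancers"),
      mix_share = c(0.25, 0.20, 0.25, 0.30),
      unit_cost = c(1000, 2000, 2500, 4000)
    )
  })
  tibble::tibble(
    country = countries,
    income_class = "lower-middle",
    male_population_m = 50,
    poverty_headcount_m = 5,
    coverage_fraction = rep_len(coverage_fraction, n),
    public_cost_share = rep_len(public_cost_share, n),
    smoking_prevalence_15_74 = 0.3,
    sticks_per_day = rep_len(sticks_per_day, n),
    smokers_table1_m = vapply(quintile_smokers, sum, numeric(1)),
    smokers_total_printed_m = vapply(quintile_smokers, sum, numeric(1)),
    price_per_pack = rep_len(price_per_pack, n),
    tax_share = rep_len(tax_share, n),
    gini = rep_len(gini, n),
    mean_income = rep_len(mean_income, n),
    frp_subset = rep_len(frp_subset, n),
    smokers_by_quintile = quintile_smokers,
    diseases = diseases
  )
}

# Independent empirical Gini (sorted-rank formula) used as a Monte-Carlo
# oracle against the closed-form lognormal Gini.
empirical_gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}
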