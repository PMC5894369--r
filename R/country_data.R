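#' Load country profiles
#'
#' Reads the country-level model inputs — demography, smoking, cigarette
#' prices and taxation, health-financing coverage, income distribution
#' parameters, smokers by income quintile, and the disease mix with unit
#' treatment costs — and validates them. With no arguments the packaged
#' inputs for the 13 middle income countries are used.
#'
#' The packaged `countries.csv` and `smokers_by_quintile.csv` transcribe the
#' published country indicators; `disease_costs_synthetic.csv` carries
#' synthetic placeholder values for the disease mix and lifetime treatment
#' cost per fatal case (the survey-derived originals are not published in the
#' main tables), and the Gini coefficients and mean per-capita incomes in
#' `countries.csv` are likewise plausible synthetic values except where the
#' source prints them. Users can substitute their own files with the same
#' schemas.
#'
#' Censored cells written as `"<x"` are parsed as the midpoint `x/2` and
#' flagged in the `censored_cells` attribute of the result.
#'
#' @param countries Path to the country indicator CSV. One row per country
#'   with columns `country`, `income_class`, `male_population_m`,
#'   `poverty_headcount_m`, `coverage_fraction`, `public_cost_share`,
#'   `smoking_prevalence_15_74`, `sticks_per_day`, `smokers_table1_m` (the
#'   separately published country count, metadata only),
#'   `smokers_total_printed_m` (the published quintile-table total, which the
#'   quintile cells must match), `price_per_pack`, `tax_share`, `gini`,
#'   `mean_income`, `frp_subset`.
#' @param quintiles Path to the smokers-by-quintile CSV with columns
#'   `country`, `quintile` (1 = poorest fifth ... 5 = richest fifth) and
#'   `smokers_m` (male cigarette smokers aged 15+, millions).
#' @param disease_costs Path to the disease mix / unit cost CSV with columns
#'   `country`, `disease`, `mix_share` and `unit_cost` ($PPP per fatal case).
#' @return A tibble with one row per country; scalar indicator columns plus
#'   list-columns `smokers_by_quintile` (numeric length 5) and `diseases`
#'   (4-row tibble of `disease`, `mix_share`, `unit_cost`). Carries the class
#'   `"smoketax_profiles"`.
#' @export
#' @examples
#' profiles <- load_country_profiles()
#' dplyr::select(profiles, country, price_per_pack, tax_share)
load_country_profiles <- function(countries = smoketax_file("countries.csv"),
                                  quintiles = smoketax_file("smokers_by_quintile.csv"),
                                  disease_costs = smoketax_file("disease_costs_synthetic.csv")) {
  raw <- read_table_checked(countries, "country table")
  require_columns(raw, c(
    "country", "income_class", "male_population_m", "poverty_headcount_m",
    "coverage_fraction", "public_cost_share", "smoking_prevalence_15_74",
    "sticks_per_day", "smokers_table1_m", "smokers_total_printed_m",
    "price_per_pack", "tax_share",
    "gini", "mean_income", "frp_subset"
  ), "country table")

  censored <- character(0)
  num_cols <- setdiff(names(raw), c("country", "income_class", "frp_subset"))
  for (col in num_cols) {
    parsed <- parse_censored(raw[[col]])
    if (any(attr(parsed, "censored"))) {
      censored <- c(censored, sprintf("%s:%s", raw$country[attr(parsed, "censored")], col))
    }
    raw[[col]] <- as.numeric(parsed)
  }
  raw$frp_subset <- as.logical(raw$frp_subset)

  qt <- read_table_checked(quintiles, "quintile table")
  require_columns(qt, c("country", "quintile", "smokers_m"), "quintile table")
  qt$smokers_m <- as.numeric(parse_censored(qt$smokers_m))
  qt_nested <- qt |>
    arrange(.data$country, .data$quintile) |>
    group_by(.data$country) |>
    summarise(smokers_by_quintile = list(.data$smokers_m), .groups = "drop")

  dc <- read_table_checked(disease_costs, "disease cost table")
  require_columns(dc, c("country", "disease", "mix_share", "unit_cost"),
                  "disease cost table")
  dc_nested <- dc |>
    mutate(mix_share = as.numeric(.data$mix_share),
           unit_cost = as.numeric(.data$unit_cost)) |>
    tidyr::nest(diseases = c("disease", "mix_share", "unit_cost"))

  profiles <- raw |>
    left_join(qt_nested, by = "country") |>
    left_join(dc_nested, by = "country")

  validate_profiles(profiles)
  attr(profiles, "censored_cells") <- censored
  class(profiles) <- c("smoketax_profiles", class(profiles))
  profiles
}

read_table_checked <- function(path, what) {
  if (!file.exists(path)) abort(sprintf("schema error in %s: file '%s' not found", what, path))
  if (file.size(path) == 0) abort(sprintf("schema error in %s: file '%s' is empty", what, path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) abort(sprintf("schema error in %s: no data rows", what))
  df
}

#' Validate a country-profile table
#'
#' Checks the model's input invariants: all fractions lie in \[0, 1\], prices
#' and consumption are positive, the four disease-mix shares sum to one, the
#' quintile smoker counts are non-negative, and their sum agrees with the
#' published country total within 2% (or within half a printed unit per cell,
#' whichever is larger, to absorb one-decimal rounding of the published
#' quintile cells).
#'
#' @param profiles A profile tibble as returned by [load_country_profiles()].
#' @return The input, invisibly; errors name the offending country and field.
#' @export
validate_profiles <- function(profiles) {
  bad <- function(country, field, msg) {
    abort(sprintf("validation error for %s, field '%s': %s", country, field, msg))
  }
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    cn <- p$country
    for (f in c("coverage_fraction", "public_cost_share",
                "smoking_prevalence_15_74", "tax_share", "gini")) {
      v <- p[[f]]
      if (is.na(v) || v < 0 || v > 1) bad(cn, f, "must be a fraction in [0, 1]")
    }
    if (p$price_per_pack <= 0) bad(cn, "price_per_pack", "must be > 0")
    if (p$sticks_per_day <= 0) bad(cn, "sticks_per_day", "must be > 0")
    if (p$mean_income <= 0) bad(cn, "mean_income", "must be > 0")
    q <- p$smokers_by_quintile[[1]]
    if (is.null(q)) bad(cn, "smokers_by_quintile", "missing quintile rows")
    if (length(q) != 5) bad(cn, "smokers_by_quintile", "need exactly 5 quintile values")
    if (any(q < 0)) bad(cn, "smokers_by_quintile", "entries must be >= 0")
    total <- p$smokers_total_printed_m
    tol <- max(0.02 * total, 5 * 0.05)
    if (abs(sum(q) - total) > tol) {
      bad(cn, "smokers_by_quintile",
          sprintf("sum %.2f disagrees with country total %.2f beyond tolerance %.2f",
                  sum(q), total, tol))
    }
    d <- p$diseases[[1]]
    if (is.null(d) || nrow(d) != 4) bad(cn, "diseases", "need exactly 4 disease rows")
    if (abs(sum(d$mix_share) - 1) > 1e-9) bad(cn, "disease_mix", "shares must sum to 1")
    if (any(d$unit_cost < 0)) bad(cn, "unit_treatment_cost", "must be >= 0")
  }
  invisible(profiles)
}

#' Baseline smokers per country
#'
#' Sums the quintile smoker counts to the country total used throughout the
#' model (the published per-quintile values are authoritative; the separate
#' published country-total row is retained only as metadata in
#' `smokers_table1_m`).
#'
#' @param profiles A profile tibble from [load_country_profiles()].
#' @return A tibble with columns `country` and `smokers_m` (millions).
#' @export
#' @examples
#' baseline_smoker_total(load_country_profiles())
baseline_smoker_total <- function(profiles) {
  profiles |>
    as_tibble() |>
    transmute(country = .data$country,
              smokers_m = purrr::map_dbl(.data$smokers_by_quintile, sum))
}

#' Write country profiles back to the fixture format
#'
#' Emits `countries.csv` and `smokers_by_quintile.csv` (and
#' `disease_costs.csv`) in the same schema that [load_country_profiles()]
#' reads, so that a written profile set round-trips to identical values.
#'
#' @param profiles A profile tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_country_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalar <- profiles |>
    as_tibble() |>
    select(-"smokers_by_quintile", -"diseases")
  qt <- profiles |>
    as_tibble() |>
    select("country", "smokers_by_quintile") |>
    tidyr::unnest_longer("smokers_by_quintile", values_to = "smokers_m") |>
    group_by(.data$country) |>
    mutate(quintile = row_number()) |>
    ungroup() |>
    select("country", "quintile", "smokers_m")
  dc <- profiles |>
    as_tibble() |>
    select("country", "diseases") |>
    tidyr::unnest("diseases")
  paths <- file.path(dir, c("countries.csv", "smokers_by_quintile.csv", "disease_costs.csv"))
  readr::write_csv(scalar, paths[1])
  readr::write_csv(qt, paths[2])
  readr::write_csv(dc, paths[3])
  invisible(paths)
}

#' Per-disease coverage overrides
#'
#' Some public financing schemes cover only particular diseases or income
#' groups; Mexico's Seguro Popular, for instance, fully covers the two
#' poorest quintiles but only for chronic obstructive pulmonary disease,
#' while the other quintiles have partial coverage for all four diseases.
#' Overrides replace the country-level `coverage_fraction` and
#' `public_cost_share` for specific (country, quintile, disease) cells.
#'
#' @param path CSV with columns `country`, `quintile`, `disease`,
#'   `coverage_fraction`, `public_cost_share`. The packaged default encodes
#'   the Mexico rule; use `NULL` for no overrides.
#' @return A tibble of overrides (possibly empty).
#' @export
load_coverage_overrides <- function(path = smoketax_file("coverage_overrides.csv")) {
  if (is.null(path)) {
    return(tibble(country = character(), quintile = integer(), disease = character(),
                  coverage_fraction = double(), public_cost_share = double()))
  }
  df <- read_table_checked(path, "coverage override table")
  require_columns(df, c("country", "quintile", "disease",
                        "coverage_fraction", "public_cost_share"),
                  "coverage override table")
  df |>
    mutate(quintile = as.integer(.data$quintile),
           coverage_fraction = as.numeric(.data$coverage_fraction),
           public_cost_share = as.numeric(.data$public_cost_share))
}
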