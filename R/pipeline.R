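#' Run a price-increase scenario end to end
#'
#' Executes the full model chain for one scenario: synthesize the age
#' structure, apply the elasticity matrix to get quitters and intensity
#' reductions, convert quitters to life years gained and deaths averted,
#' apportion deaths across the four disease groups, price the averted
#' treatment (total and out of pocket), evaluate catastrophic-expenditure
#' and impoverishment aversion under the lognormal income model (for the
#' subset of countries without effective universal coverage), and account
#' the additional excise revenue. Deterministic given the scenario seed.
#'
#' The future-smoker cohort (when enabled) contributes quitters, life years
#' and deaths averted at the youngest-age benefit, but no baseline
#' consumption and hence no tax revenue.
#'
#' @param profiles A profile tibble from [load_country_profiles()].
#' @param scen A [scenario()] object.
#' @param overrides Coverage overrides (default the packaged Mexico rule);
#'   `NULL` for none.
#' @param schedule Life-year schedule (default [fit_life_year_schedule()]).
#' @param death_risk Probability a continuing smoker dies of smoking
#'   (default 0.5).
#' @return A `smoketax_result`: a list with `outcomes` (tibble per country x
#'   quintile: `smokers_before`, `quitters`, `life_years`, `deaths_averted`,
#'   all millions; `cost_averted_total`, `cost_averted_oop`, $PPP millions;
#'   `catastrophic_averted`, `poverty_averted`, millions of men;
#'   `extra_tax`, $PPP billions), `strata` (the age-resolved detail),
#'   `scenario` and `schedule`.
#' @export
#' @examples
#' res <- run_scenario(load_country_profiles(), scenario(seed = 1))
#' glance(res)
run_scenario <- function(profiles, scen = scenario(), overrides = load_coverage_overrides(),
                         schedule = fit_life_year_schedule(), death_risk = 0.5) {
  stopifnot(inherits(scen, "smoketax_scenario"))
  pt <- as_tibble(profiles)
  if (!is.null(scen$include_countries)) {
    missing <- setdiff(scen$include_countries, pt$country)
    if (length(missing) > 0) {
      abort(sprintf("unknown countries in include_countries: %s",
                    paste(missing, collapse = ", ")))
    }
    pt <- filter(pt, .data$country %in% scen$include_countries)
  }
  if (isTRUE(scen$include_female)) {
    fs <- scen$female_shares
    pt <- pt |>
      mutate(smokers_by_quintile = purrr::map2(
        .data$smokers_by_quintile, .data$country,
        function(q, cn) if (cn %in% names(fs)) q / (1 - fs[[cn]]) else q
      ))
  }

  strata <- synthesize_age_structure(pt, jitter = scen$jitter, seed = scen$seed)

  # elasticity: one matrix for all countries, or per-country rescaled
  per_country_matrix <- function(cn) {
    e <- scen$elasticity
    if (is.numeric(e)) {
      if (is.null(names(e)) || !cn %in% names(e)) {
        abort(sprintf("no country elasticity supplied for %s", cn))
      }
      scale_elasticity_matrix(build_elasticity_matrix(), e[[cn]])
    } else e
  }

  response <- strata |>
    group_by(.data$country) |>
    group_modify(function(df, key) {
      m <- per_country_matrix(key$country)
      df |>
        mutate(elasticity = effective_elasticity(m, .data$age_band, .data$quintile),
               quit_frac = quit_fraction(.data$elasticity, scen$price_increase,
                                         scen$quit_share),
               quitters = .data$smokers * .data$quit_frac)
    }) |>
    ungroup()

  if (scen$initiation_fraction > 0) {
    future <- synthesize_future_cohort(pt, scen$initiation_fraction,
                                       seed = scen$seed) |>
      mutate(age_band = "future", sticks_per_day = 0) |>
      rename(smokers = "future_smokers")
    future <- future |>
      group_by(.data$country) |>
      group_modify(function(df, key) {
        m <- per_country_matrix(key$country)
        df |>
          mutate(elasticity = effective_elasticity(m, .data$age_band, .data$quintile),
                 quit_frac = quit_fraction(.data$elasticity, scen$price_increase,
                                           scen$quit_share),
                 quitters = .data$smokers * .data$quit_frac)
      }) |>
      ungroup()
    response <- bind_rows(response, future)
  }

  # health outcomes; the future cohort takes the youngest-band benefit
  sched <- as_tibble(schedule)
  top_band <- sched$age_band[which.max(sched$life_years_per_quitter)]
  lookup_band <- ifelse(response$age_band == "future", top_band, response$age_band)
  response <- response |>
    mutate(
      life_years = .data$quitters *
        sched$life_years_per_quitter[match(lookup_band, sched$age_band)],
      deaths_averted = .data$quitters * death_risk *
        sched$life_years_per_quitter[match(lookup_band, sched$age_band)] /
        max(sched$life_years_per_quitter)
    )

  disease_mix <- pt |>
    select("country", "diseases") |>
    tidyr::unnest("diseases")
  unit_costs <- disease_mix |> select("country", "disease", "unit_cost")
  oop <- oop_share(pt, overrides)

  by_disease <- response |>
    select("country", "quintile", "age_band", "deaths_averted") |>
    apportion_deaths(disease_mix |> select("country", "disease", "mix_share"))
  costs <- costs_averted(by_disease, unit_costs, oop)

  # financial risk protection: averted fatal cases, priced at the mix- and
  # coverage-weighted out-of-pocket cost per case; restricted by policy to
  # the low-coverage country subset
  oop_cost_case <- disease_mix |>
    tidyr::expand_grid(quintile = 1:5) |>
    left_join(oop, by = c("country", "quintile", "disease")) |>
    group_by(.data$country, .data$quintile) |>
    summarise(oop_per_case = sum(.data$mix_share * .data$unit_cost * .data$oop_share),
              .groups = "drop")

  frp <- response |>
    group_by(.data$country, .data$quintile) |>
    summarise(cases = sum(.data$deaths_averted) * scen$case_multiplier,
              .groups = "drop") |>
    left_join(oop_cost_case, by = c("country", "quintile")) |>
    left_join(pt |> select("country", "gini", "mean_income", "frp_subset"),
              by = "country") |>
    group_by(.data$country) |>
    group_modify(function(df, key) {
      if (!df$frp_subset[1]) {
        return(mutate(df, catastrophic_averted = 0, poverty_averted = 0))
      }
      model <- lognormal_from_gini(df$gini[1], df$mean_income[1])
      mutate(df,
        catastrophic_averted = catastrophic_averted(.data$cases, .data$oop_per_case,
                                                    model, .data$quintile),
        poverty_averted = poverty_averted(.data$cases, .data$oop_per_case, model,
                                          .data$quintile,
                                          poverty_line_per_day = scen$poverty_line_per_day)
      )
    }) |>
    ungroup() |>
    select("country", "quintile", "catastrophic_averted", "poverty_averted")

  tax <- response |>
    filter(.data$age_band != "future") |>
    left_join(pt |> select("country", "price_per_pack", "tax_share"), by = "country") |>
    mutate(extra_tax_m = extra_tax_revenue(
      .data$smokers, .data$sticks_per_day, .data$price_per_pack, .data$tax_share,
      .data$elasticity, scen$price_increase, scen$quit_share
    )) |>
    group_by(.data$country, .data$quintile) |>
    summarise(extra_tax = sum(.data$extra_tax_m) / 1000, .groups = "drop")

  outcomes <- response |>
    group_by(.data$country, .data$quintile) |>
    summarise(
      smokers_before = sum(.data$smokers[.data$age_band != "future"]),
      quitters = sum(.data$quitters),
      life_years = sum(.data$life_years),
      deaths_averted = sum(.data$deaths_averted),
      .groups = "drop"
    ) |>
    left_join(costs, by = c("country", "quintile")) |>
    left_join(frp, by = c("country", "quintile")) |>
    left_join(tax, by = c("country", "quintile")) |>
    arrange(match(.data$country, pt$country), .data$quintile)

  structure(
    list(outcomes = outcomes, strata = response, scenario = scen,
         schedule = sched),
    class = "smoketax_result"
  )
}

#' Published outcome table for replay mode
#'
#' Loads the published country-by-quintile outcome table (smokers before the
#' price rise, life years gained, disease cost averted, additional tax
#' revenue) so that the aggregation layer can be verified exactly against
#' the printed aggregates without rerunning the model ("replay mode").
#' Censored cells printed as `"<0.1"` enter as 0.05 and are flagged in the
#' `censored_cells` attribute.
#'
#' @param path CSV path; default the packaged transcription.
#' @return A tibble `country`, `quintile`, `smokers_before` (millions),
#'   `life_years` (millions), `cost_averted_total` ($PPP millions),
#'   `extra_tax` ($PPP billions).
#' @export
#' @examples
#' summarize_outcomes(replay_outcomes())
replay_outcomes <- function(path = smoketax_file("table2_outcomes.csv")) {
  df <- read_table_checked(path, "outcome table")
  require_columns(df, c("country", "quintile", "smokers_before_m",
                        "life_years_m", "cost_averted_musd", "extra_tax_busd"),
                  "outcome table")
  censored <- character(0)
  out <- tibble(country = df$country, quintile = as.integer(df$quintile))
  for (cols in list(c("smokers_before_m", "smokers_before"),
                    c("life_years_m", "life_years"),
                    c("cost_averted_musd", "cost_averted_total"),
                    c("extra_tax_busd", "extra_tax"))) {
    v <- parse_censored(df[[cols[1]]])
    if (any(attr(v, "censored"))) {
      censored <- c(censored,
                    sprintf("%s:q%s:%s", df$country[attr(v, "censored")],
                            df$quintile[attr(v, "censored")], cols[2]))
    }
    out[[cols[2]]] <- as.numeric(v)
  }
  attr(out, "censored_cells") <- censored
  out
}

#' Distributional summary of an outcome table
#'
#' Collapses a country-by-quintile outcome table to the distributional
#' headline statistics: the cross-country total of each outcome, the sums in
#' the bottom and top comparison groups, their ratio (reported to one
#' decimal), and the per-country bottom-group share of the country total in
#' percent (nearest integer), summarised by its median and min-max range
#' across countries.
#'
#' @param outcomes A `smoketax_result` or a tibble with `country`, `quintile`
#'   and numeric outcome columns (e.g. from [replay_outcomes()]).
#' @param groups Length-2 integer vector: the (bottom, top) comparison
#'   quintiles; default `c(1, 5)`.
#' @return A `smoketax_summary`: list with `stats` (one row per outcome:
#'   `total`, `bottom_sum`, `top_sum`, `bottom_top_ratio`,
#'   `bottom_share_median_pct`, `bottom_share_min_pct`,
#'   `bottom_share_max_pct`), `shares` (per-country bottom/top shares, %),
#'   `groups` and `n_countries`.
#' @export
#' @examples
#' s <- summarize_outcomes(replay_outcomes())
#' s$stats
summarize_outcomes <- function(outcomes, groups = c(1, 5)) {
  if (inherits(outcomes, "smoketax_result")) outcomes <- outcomes$outcomes
  if (nrow(outcomes) == 0) abort("empty outcome table")
  value_cols <- setdiff(names(outcomes)[vapply(outcomes, is.numeric, logical(1))],
                        "quintile")
  long <- outcomes |>
    tidyr::pivot_longer(dplyr::all_of(value_cols), names_to = "outcome",
                        values_to = "value")
  shares <- long |>
    group_by(.data$outcome, .data$country) |>
    summarise(
      country_total = sum(.data$value),
      bottom = sum(.data$value[.data$quintile == groups[1]]),
      top = sum(.data$value[.data$quintile == groups[2]]),
      .groups = "drop"
    ) |>
    mutate(
      bottom_share_pct = ifelse(.data$country_total > 0,
                                round(100 * .data$bottom / .data$country_total), NA_real_),
      top_share_pct = ifelse(.data$country_total > 0,
                             round(100 * .data$top / .data$country_total), NA_real_)
    )
  stats <- shares |>
    group_by(.data$outcome) |>
    summarise(
      total = sum(.data$country_total),
      bottom_sum = sum(.data$bottom),
      top_sum = sum(.data$top),
      bottom_top_ratio = ifelse(sum(.data$top) > 0,
                                round(sum(.data$bottom) / sum(.data$top), 1), NA_real_),
      bottom_share_median_pct = median(.data$bottom_share_pct, na.rm = TRUE),
      bottom_share_min_pct = min(.data$bottom_share_pct, na.rm = TRUE),
      bottom_share_max_pct = max(.data$bottom_share_pct, na.rm = TRUE),
      .groups = "drop"
    ) |>
    arrange(match(.data$outcome, value_cols))
  structure(
    list(stats = stats, shares = shares, groups = groups,
         n_countries = dplyr::n_distinct(outcomes$country)),
    class = "smoketax_summary"
  )
}

#' Run the standard sensitivity analyses
#'
#' Reruns the model under the published sensitivity scenarios: price
#' increases of 25% and 100%, exclusion of China and India (the two
#' countries holding over two thirds of the smokers), inclusion of female
#' smokers in the three countries where they are numerous (Chile 46%,
#' Colombia and Mexico 29% of smokers), and country-specific overall
#' elasticities.
#'
#' @param profiles A profile tibble.
#' @param base_scenario The reference [scenario()].
#' @param labels Subset of
#'   `c("dp25", "dp100", "excl_CN_IN", "incl_female", "country_elasticities")`.
#' @param country_elasticities Named numeric vector of per-country overall
#'   elasticities; default reads the packaged synthetic values.
#' @param ... Passed to [run_scenario()].
#' @return A named list; each element has `scenario`, `result` and `summary`.
#' @export
sensitivity_suite <- function(profiles, base_scenario = scenario(),
                              labels = c("dp25", "dp100", "excl_CN_IN",
                                         "incl_female", "country_elasticities"),
                              country_elasticities = NULL, ...) {
  known <- c("dp25", "dp100", "excl_CN_IN", "incl_female", "country_elasticities")
  bad <- setdiff(labels, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown sensitivity label(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(country_elasticities)) {
    ce <- readr::read_csv(smoketax_file("country_elasticities_synthetic.csv"),
                          show_col_types = FALSE, progress = FALSE)
    country_elasticities <- stats::setNames(ce$elasticity, ce$country)
  }
  variant <- function(label) {
    s <- base_scenario
    switch(label,
      dp25 = s$price_increase <- 0.25,
      dp100 = s$price_increase <- 1.0,
      excl_CN_IN = s$include_countries <-
        setdiff(as_tibble(profiles)$country, c("China", "India")),
      incl_female = s$include_female <- TRUE,
      country_elasticities = s$elasticity <- country_elasticities
    )
    s
  }
  out <- lapply(labels, function(lab) {
    s <- variant(lab)
    res <- run_scenario(profiles, s, ...)
    list(scenario = s, result = res, summary = summarize_outcomes(res))
  })
  stats::setNames(out, labels)
}

#' Write report files for a model run
#'
#' Emits the result in a published-table shape: one file per outcome block
#' (countries x quintiles), a financial-protection block (catastrophic and
#' poverty aversion by quintile for the low-coverage country subset), and a
#' bottom-versus-top share block. Values are rounded as in the published
#' tables: one decimal for counts in millions, integers for percentages.
#'
#' @param result A `smoketax_result` (or a plain outcome tibble).
#' @param format One of `"csv"`, `"json"`, `"markdown"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(result, format = c("csv", "json", "markdown"), dir = ".") {
  format <- match.arg(format)
  outcomes <- if (inherits(result, "smoketax_result")) result$outcomes else result
  summ <- summarize_outcomes(outcomes)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  value_cols <- setdiff(names(outcomes)[vapply(outcomes, is.numeric, logical(1))],
                        "quintile")

  blocks <- lapply(value_cols, function(col) {
    outcomes |>
      select("country", "quintile", dplyr::all_of(col)) |>
      mutate(across(dplyr::all_of(col), ~ round(.x, 1))) |>
      tidyr::pivot_wider(names_from = "quintile", values_from = dplyr::all_of(col),
                         names_prefix = "q")
  })
  names(blocks) <- value_cols

  frp_cols <- intersect(c("catastrophic_averted", "poverty_averted"), value_cols)
  fig1 <- if (length(frp_cols) > 0) {
    outcomes |>
      mutate(.frp = rowSums(across(dplyr::all_of(frp_cols)))) |>
      group_by(.data$country) |>
      filter(sum(.data$.frp) > 0) |>
      ungroup() |>
      select("country", "quintile", dplyr::all_of(frp_cols))
  } else NULL
  fig2 <- summ$shares |>
    select("outcome", "country", "bottom_share_pct", "top_share_pct")

  paths <- character(0)
  emit <- function(obj, stem) {
    p <- file.path(dir, paste0(stem, ".", switch(format, csv = "csv",
                                                 json = "json", markdown = "md")))
    switch(format,
      csv = readr::write_csv(obj, p),
      json = jsonlite::write_json(obj, p, dataframe = "rows", auto_unbox = TRUE,
                                  digits = NA),
      markdown = writeLines(markdown_table(obj), p)
    )
    p
  }
  for (nm in names(blocks)) paths <- c(paths, emit(blocks[[nm]], paste0("block_", nm)))
  if (!is.null(fig1) && nrow(fig1) > 0) {
    paths <- c(paths, emit(fig1, "financial_protection"))
  }
  paths <- c(paths, emit(fig2, "group_shares"),
             emit(summ$stats, "summary_stats"))
  invisible(paths)
}

markdown_table <- function(df) {
  df <- as.data.frame(df)
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}

#' Read a scenario configuration from YAML
#'
#' The YAML file may set any [scenario()] argument (under `scenario:`) and
#' input paths (under `paths:`, keys `countries`, `quintiles`,
#' `disease_costs`, `overrides`), defaulting to the packaged fixtures.
#'
#' @param path YAML file path.
#' @return A list with `profiles`, `scenario` and `overrides`, ready for
#'   [run_scenario()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  paths <- cfg$paths %||% list()
  profiles <- load_country_profiles(
    countries = paths$countries %||% smoketax_file("countries.csv"),
    quintiles = paths$quintiles %||% smoketax_file("smokers_by_quintile.csv"),
    disease_costs = paths$disease_costs %||% smoketax_file("disease_costs_synthetic.csv")
  )
  overrides <- if (!is.null(paths$overrides)) load_coverage_overrides(paths$overrides)
               else load_coverage_overrides()
  sc_args <- cfg$scenario %||% list()
  if (!is.null(sc_args$female_shares)) {
    sc_args$female_shares <- unlist(sc_args$female_shares)
  }
  scen <- do.call(scenario, sc_args)
  list(profiles = profiles, scenario = scen, overrides = overrides)
}
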