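#' Plot bottom- versus top-group shares of each outcome
#'
#' A bar chart of the share of each outcome accruing to the bottom and top
#' comparison quintiles, the figure that makes the distributional point: the
#' poorest fifth receives the largest share of the health and
#' financial-protection benefits while paying the smallest share of the
#' additional tax.
#'
#' @param summary A `smoketax_summary` from [summarize_outcomes()].
#' @return A ggplot object.
#' @export
plot_benefit_shares <- function(summary) {
  stopifnot(inherits(summary, "smoketax_summary"))
  df <- summary$stats |>
    mutate(
      bottom = 100 * .data$bottom_sum / .data$total,
      top = 100 * .data$top_sum / .data$total
    ) |>
    select("outcome", "bottom", "top") |>
    tidyr::pivot_longer(c("bottom", "top"), names_to = "group",
                        values_to = "share_pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$share_pct,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 20, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Share of total (%)", fill = "Income group",
      title = "Share of outcomes accruing to bottom vs top income quintile",
      caption = "Dashed line: 20%, the share expected with no income gradient"
    )
}

#' Plot financial risk protection by quintile
#'
#' Men avoiding catastrophic health expenditure and extreme poverty, by
#' income quintile, for the countries in the low-coverage subset where these
#' outcomes are computed.
#'
#' @param result A `smoketax_result`.
#' @return A ggplot object.
#' @export
plot_financial_protection <- function(result) {
  stopifnot(inherits(result, "smoketax_result"))
  df <- result$outcomes |>
    group_by(.data$country) |>
    filter(sum(.data$catastrophic_averted + .data$poverty_averted) > 0) |>
    ungroup() |>
    select("country", "quintile", "catastrophic_averted", "poverty_averted") |>
    tidyr::pivot_longer(c("catastrophic_averted", "poverty_averted"),
                        names_to = "measure", values_to = "men_m")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$quintile), y = .data$men_m,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~country, scales = "free_y") +
    ggplot2::labs(
      x = "Income quintile (1 = poorest)", y = "Men (millions)",
      fill = NULL,
      title = "Catastrophic health expenditure and extreme poverty averted"
    )
}

#' Plot the cessation benefit schedule
#'
#' Life years gained per quitter by age band, after monotone smoothing of
#' the interval estimates onto the 5-year grid.
#'
#' @param schedule A schedule from [fit_life_year_schedule()].
#' @return A ggplot object.
#' @export
plot_life_year_schedule <- function(schedule = fit_life_year_schedule()) {
  df <- as_tibble(schedule) |>
    left_join(age_bands(), by = "age_band")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$life_years_per_quitter)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Age at cessation (band midpoint, years)",
                  y = "Life years gained per quitter",
                  title = "Cessation benefit schedule")
}

#' @rdname plot_benefit_shares
#' @param object A `smoketax_summary`.
#' @param ... Unused.
#' @method autoplot smoketax_summary
#' @export
autoplot.smoketax_summary <- function(object, ...) {
  plot_benefit_shares(object)
}

#' @rdname plot_financial_protection
#' @param object A `smoketax_result`.
#' @param ... Unused.
#' @method autoplot smoketax_result
#' @export
autoplot.smoketax_result <- function(object, ...) {
  plot_financial_protection(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
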