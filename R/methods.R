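#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model run
#'
#' Returns the country-by-quintile outcome table of a [run_scenario()]
#' result as a tibble, one row per (country, quintile).
#'
#' @param x A `smoketax_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy smoketax_result
#' @export
tidy.smoketax_result <- function(x, ...) {
  as_tibble(x$outcomes)
}

#' One-row summary of a model run
#'
#' Cross-country totals of every outcome plus the scenario's main levers.
#'
#' @param x A `smoketax_result`.
#' @param ... Unused.
#' @return A one-row tibble: totals for all outcomes (same units as the
#'   outcome table), `n_countries`, `price_increase`, `quit_share`, `seed`.
#' @method glance smoketax_result
#' @export
glance.smoketax_result <- function(x, ...) {
  value_cols <- setdiff(names(x$outcomes)[vapply(x$outcomes, is.numeric, logical(1))],
                        "quintile")
  totals <- x$outcomes |> summarise(across(dplyr::all_of(value_cols), sum))
  totals |>
    mutate(n_countries = dplyr::n_distinct(x$outcomes$country),
           price_increase = x$scenario$price_increase,
           quit_share = x$scenario$quit_share,
           seed = x$scenario$seed)
}

#' Tidy a distributional summary
#'
#' @param x A `smoketax_summary` from [summarize_outcomes()].
#' @param ... Unused.
#' @return The per-outcome statistics tibble.
#' @method tidy smoketax_summary
#' @export
tidy.smoketax_summary <- function(x, ...) {
  x$stats
}

#' @export
print.smoketax_result <- function(x, ...) {
  cat(sprintf(
    "<smoketax_result> %d countries, price increase +%.0f%%, seed %d\n",
    dplyr::n_distinct(x$outcomes$country), 100 * x$scenario$price_increase,
    x$scenario$seed
  ))
  g <- glance(x)
  cat(sprintf("  quitters %.1fM | life years %.0fM | deaths averted %.1fM\n",
              g$quitters, g$life_years, g$deaths_averted))
  cat(sprintf("  costs averted $%.0fM (oop $%.0fM) | extra tax $%.1fbn\n",
              g$cost_averted_total, g$cost_averted_oop, g$extra_tax))
  invisible(x)
}

#' @export
print.smoketax_summary <- function(x, ...) {
  cat(sprintf("<smoketax_summary> %d countries, comparison quintiles %d vs %d\n",
              x$n_countries, x$groups[1], x$groups[2]))
  print(x$stats)
  invisible(x)
}

#' @export
print.smoketax_scenario <- function(x, ...) {
  el <- if (is.numeric(x$elasticity)) "country-specific"
        else sprintf("matrix (mean target %.2f)", attr(x$elasticity, "mean_target") %||% -0.4)
  cat(sprintf(
    "<smoketax_scenario> +%.0f%% price, quit share %.2f, elasticity %s, seed %d\n",
    100 * x$price_increase, x$quit_share, el, x$seed
  ))
  invisible(x)
}
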