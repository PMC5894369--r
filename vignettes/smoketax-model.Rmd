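---
title: "The smoketax model: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The smoketax model: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoketax)
library(dplyr)
```

`smoketax` is a static compartmental cohort model of a one-time cigarette
price increase, in the extended cost-effectiveness analysis (ECEA)
tradition: alongside health outcomes it tracks who — by income quintile —
receives the financial-risk-protection benefits and who pays the extra tax.
This vignette is the package's own account of the model: what is computed,
under which assumptions, which parameters matter, and where the design was
genuinely open.

## The causal chain

One model run (`run_scenario()`) walks a fixed chain:

1. **Population.** Male cigarette smokers aged 15+ per country and income
   quintile (packaged inputs), resolved into 5-year age bands from 15 to 90
   by the synthetic generator (below).
2. **Demand response.** For a fractional price rise $\Delta p$ and stratum
   elasticity $\varepsilon$, consumption falls by
   $\min(1, |\varepsilon|\,\Delta p)$ (an *arc* response — the elasticity is
   applied directly to the fractional change, matching the headline
   arithmetic "−0.4 elasticity, +50 % price, −20 % consumption"). A share
   $s$ (default 0.5) of the fall is complete cessation
   (`quit_fraction()`); the complement is fewer cigarettes per day among
   continuing smokers (`intensity_reduction()`), for which **no health
   benefit is credited** — a deliberately conservative exclusion.
3. **Health.** Each quitter gains the life years of the cessation-age
   schedule; deaths averted decay with age proportionally to that schedule
   from 0.5 per quitter at the youngest ages.
4. **Costs.** Averted deaths are split across COPD, stroke, heart disease
   and cancers (tuberculosis ignored) and priced at per-case treatment
   costs; the out-of-pocket (OOP) part is
   $1 - \text{coverage} \times \text{public cost share}$, with per-disease,
   per-quintile overrides (Mexico's Seguro Popular covers only COPD, fully,
   for the two poorest quintiles).
5. **Financial risk protection.** With lognormal incomes truncated to the
   quintile's quantile interval, a case is catastrophic when OOP cost
   exceeds 10 % of annual income and impoverishing when it pushes income
   below \$1.90/day × 365.
6. **Revenue.** Full pass-through: the excise rises by
   $\Delta p \times \text{price}$; extra revenue is what continuing smokers
   pay on their reduced consumption at the new tax per pack, minus the
   baseline.

The model is *static*: it prices the cumulative, undiscounted consequences
of a single price step for the current smoker cohort. No multi-year
dynamics, discounting, productivity losses, second-hand smoke, or non-
cigarette tobacco (bidis, oral) are modelled.

## The elasticity matrix

Price responsiveness is roughly twice as high in smokers aged 15–24 and in
the poorest quintile as in older, richer smokers. The default matrix
(`build_elasticity_matrix()`) pins the two published anchor cells,
$\varepsilon(15\text{–}24, q_1) = -1.27$ and
$\varepsilon(25{+}, q_5) = -0.24$, and fills the rest by a declared
convention: the 25+ row interpolates geometrically from $-1.27/2$ at the
bottom quintile to $-0.24$ at the top (constant ratio
$(0.24/0.635)^{1/4} \approx 0.784$ per quintile step), and the young row is
twice the old row with its bottom cell pinned exactly. The exact
interior weights used in the original analysis are not published; the
geometric rule is the package's own choice because it pins both anchors,
preserves both monotone gradients, and has one free parameter (the age
ratio). A user matrix can be injected from CSV
(`read_elasticity_matrix()`), and per-country overall elasticities rescale
every cell by $\varepsilon_c / (-0.4)$.

The smoker-weighted mean of the default matrix over the synthetic
population is reported by `mean_realized_elasticity()` (about −0.47 under
default weights); it is *not* renormalised to hit −0.4 exactly, since
whether the original analysis did so is not stated.

```{r matrix}
build_elasticity_matrix() |> tidyr::pivot_wider(names_from = quintile,
                                                values_from = elasticity)
```

## The cessation benefit schedule

The interval estimates — 10 life years regained for cessation before 30,
then 9 (30–44), 6 (45–64), 3 (65+) — are smoothed onto the 5-year grid by a
monotone shape-preserving piecewise cubic (Fritsch–Carlson, `splinefun(...,
method = "monoH.FC")`) through the interval midpoints (22.5, 10),
(37.5, 9), (55, 6), (75, 3), with constant extrapolation outside. A
smoothing spline was deliberately *not* used: monotone non-increase of the
grid with age is an invariant of the model, and shape-preserving
interpolation guarantees it; placing knots at interval midpoints is a
declared convention. Deaths averted per quitter are anchored at 0.5 (half
of persistent smokers die of smoking, losing ~10 years on average) for the
youngest band and scaled by `schedule / max(schedule)` with age — the
original age propagation is unpublished, so this grid-proportional rule is
the package's choice, configurable through `death_risk` and a replacement
schedule.

## The synthetic population generator

Only quintile *totals* of smokers are published per country; the
age-by-quintile survey tables behind the original analysis are not. The
generator (`synthesize_age_structure()`) therefore allocates each quintile
total across bands proportionally to a weight curve — by default triangular,
rising to a peak at 35–39 and reaching zero above age 84, a stylised adult
male smoking-prevalence shape for these countries — with optional Dirichlet
jitter for sensitivity work. Quintile totals are conserved *exactly* for
every weight choice, jitter level and seed, so every downstream conservation
property is testable. Per-country random substreams are derived by hashing
the country name into the top-level seed, making results independent of
country order.

What the generator does **not** emulate: real between-country differences
in the age profile of smoking, age-varying daily consumption (sticks/day is
the country mean in every stratum, as only the mean is published — a
per-quintile gradient is a config knob), and cohort dynamics. Passing tests
therefore validate the *model arithmetic* under a realistic stand-in
population, not the original survey inputs; model totals that depend on the
age structure (life years, deaths) should be read as reproducing the
published magnitudes, not the published decimals. The future-smoker cohort
(children under 15 who would have initiated) defaults to **off**
(`initiation_fraction = 0`) because its size is not quantified in the
published analysis; when enabled it takes the youngest-age elasticity and
benefit and contributes no tax revenue.

## The income model and financial risk protection

Incomes are lognormal per country: for Gini $G$,
$\sigma = \sqrt{2}\,\Phi^{-1}((G+1)/2)$ and
$\mu = \ln(\bar y) - \sigma^2/2$, which reproduces both $G$ and the mean
$\bar y$ exactly ($G = 2\Phi(\sigma/\sqrt 2) - 1$ round-trips to 1e−6 in
the tests). Quintiles are *population* quantiles — equal fifths of persons,
not of income — so quintile $q$ is the distribution truncated to
$[(q-1)/5,\, q/5]$. The catastrophic and impoverishment probabilities are
evaluated with the closed-form lognormal CDF on that interval (exact, to
floating point), and are cross-checked in the tests against a $10^6$-sample
Monte-Carlo oracle built on `sample_quintile_incomes()` (agreement within 3
standard errors). Degenerate inputs are well-defined: $G = 0$ puts all mass
at the mean; zero OOP cost averts nothing; a population already below the
poverty line cannot newly fall below it.

Two policy-level conventions follow the published analysis: catastrophic
and poverty aversion are computed **only** for the seven countries without
effective universal health coverage (India, Indonesia, Bangladesh, the
Philippines, Vietnam, China, and Mexico for its high OOP costs) — the other
six report zero *by policy*, not as a model outcome; and the case count is
averted **fatal** cases (a non-fatal multiplier, `case_multiplier`, is a
config knob defaulting to 1, since the published choice is not stated).

## Tax arithmetic

The printed "% increase in the excise rate" equals $100/\text{tax share}$
for all 13 countries, which under full pass-through corresponds to a
baseline excise equal to **half** the total tax share. The package adopts
`excise_fraction_of_tax = 0.5` as a documented, configurable assumption; it
reproduces all 13 printed cells exactly
(`excise_rate_increase_pct()`).

One caveat the tests pin down: the claim "the extra revenue per pack
outweighs the reduced demand" holds throughout the operative region (it is
guaranteed for $|\varepsilon|\,\Delta p \lesssim 0.6$ at these tax shares),
but *not* at extreme corners — at $\varepsilon = -1, \Delta p = 1$ the
surviving consumption (25 %) is too small for the tripled tax per pack, and
revenue falls; with the anchored matrix at $\Delta p = 1$ the
youngest/poorest strata (and the bottom quintile of China in aggregate) show
negative marginal revenue. This is the model's own arithmetic, reported as
such.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `price_increase` | 0.5 | fraction | reference policy; 0.25/1.0 in sensitivity suite |
| `quit_share` | 0.5 | fraction | half of the consumption response is cessation |
| elasticity anchors | −1.27 / −0.24 | — | published matrix corners |
| `age_ratio` | 2 | — | young ≈ twice as responsive |
| life-year knots | 10/9/6/3 | years | cessation-age benefit estimates |
| `death_risk` | 0.5 | probability | half of persistent smokers die of smoking |
| catastrophic threshold | 0.1 | fraction of income | WHO definition |
| `poverty_line_per_day` | 1.90 | $PPP/day | World Bank definition, × 365 |
| `excise_fraction_of_tax` | 0.5 | fraction | reproduces all printed rate increases |
| `case_multiplier` | 1 | cases/death | fatal cases only |
| `initiation_fraction` | 0 | fraction | future cohort unquantified, off |

## Data provenance and validation conventions

The packaged `countries.csv` and the quintile and outcome tables transcribe
published values. Three inputs are **synthetic placeholders**, marked as
such in file names and docs, because the originals are not
published alongside the main country tables: the disease-mix shares and unit treatment costs
(`disease_costs_synthetic.csv`; same mix everywhere, unit costs scaled to
country income), the per-country Ginis and mean incomes in `countries.csv`
(World-Bank-ballpark figures; China 0.46 and Brazil 0.53 are published),
and the country-specific elasticities
(`country_elasticities_synthetic.csv`, literature-ballpark). All are
replaceable by user files with the same schema.

Two conventions absorb print-rounding: quintile cells are validated against
the published country total within 2 % *or* half a printed unit per cell
(whichever is larger — five cells printed "0.1" may sum to 0.5 against a
printed total of 0.6); and cells printed "<0.1" enter as the midpoint 0.05
and are flagged (`censored_cells` attribute, echoed by the CLI). For the
same reason, medians and ratios recomputed from printed one-decimal cells
in replay mode are asserted to ±1 percentage point / ±0.15 rather than
exactly (e.g. the printed life-year ratio 6.7 recomputes as 6.6, and the
printed tax-share median 10 % as 11 %, from rounded cells).

The published headline *model* outputs (67 M quitters, 449 M life years)
are not exactly recoverable from the main published inputs alone — they
depend on the unpublished age-by-quintile prevalence — so the package
separates **replay mode** (`replay_outcomes()`: aggregation of the
published outcome table, verified exactly) from **model mode**
(`run_scenario()`: the full chain under the synthetic population, which
lands at 57.5 M quitters and 448 M life years with default settings —
the right magnitudes, with the life-year total close and the bottom-quintile
life-year share at 31–32 % against the printed 31 %).

## Problem sizes and determinism

Default analyses use 13 countries × 5 quintiles × 15 age bands = 975
strata and run in well under a second; the Monte-Carlo oracle tests draw
$10^6$ incomes per case. Everything stochastic (jitter, income sampling)
is governed by one integer seed; two runs with the same seed are identical,
and per-country hashing keeps substreams stable under reordering or
subsetting of countries.

## Known limitations

- Static, undiscounted, single-cohort accounting; no initiation dynamics.
- The synthetic age structure is a stylised stand-in; country-specific age
  patterns will move age-sensitive totals.
- No productivity or second-hand-smoke effects; no bidi/oral tobacco; no
  smuggling, down-trading or employment responses.
- Financial-protection results inherit the lognormal income assumption and
  the synthetic Gini/mean-income placeholders where the true values are
  unpublished.
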