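Package: smoketax
Title: Extended Cost-Effectiveness Analysis of Cigarette Price Increases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A static compartmental cohort model of large one-time cigarette
    price increases in middle income countries. Converts a price shock into
    quitting and reduced smoking intensity through an age-by-income-quintile
    price-elasticity matrix, then into life years gained, smoking-attributable
    deaths averted, disease treatment costs averted (total and out-of-pocket),
    men avoiding catastrophic health expenditure and extreme poverty (via a
    Gini-parameterised lognormal income model), and additional excise revenue.
    Includes packaged country inputs for 13 middle income countries, a
    synthetic age-structure generator, distributional summaries by income
    quintile, a sensitivity-analysis suite, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
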