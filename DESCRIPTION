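Package: fgmcprev
Title: Indirect Estimation of Female Genital Mutilation/Cutting Prevalence
    and Risk in a Diaspora Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the extrapolation model used to estimate the magnitude
    of female genital mutilation/cutting (FGM/C) in a diaspora population from
    population-register microdata and origin-country survey prevalences.
    Individual records are classified into analysis cohorts by generation, age
    at arrival and the origin country's customary cutting-age window;
    origin-country prevalence for the 15-49 and 15-19 cohorts is then
    extrapolated to estimate women and girls already subjected to FGM/C, girls
    potentially at risk, girls at risk under low and high migration-scenario
    assumptions, and type-III (infibulation) shares. Includes a seeded
    synthetic-register generator that hits requested per-country cohort
    marginals exactly, statistical-disclosure tools (small-cell suppression,
    small-country pooling), disclosure-safe table rendering and a full
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
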