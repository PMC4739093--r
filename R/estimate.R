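#' Scenario and convention configuration for the extrapolation estimator
#'
#' Collects the knobs of the extrapolation model:
#'
#' * `reference_date` — the date the population snapshot refers to.
#' * `acculturation_factor_gen2` — the migration and acculturation impact
#'   factor `f` applied to second-generation girls in the risk model, in
#'   `[0, 1]`. `f = 1` reproduces the low-risk scenario (migration removes
#'   the second generation's risk entirely), `f = 0` the high-risk scenario
#'   (migration changes nothing). The canonical model treats `f` as binary;
#'   intermediate values are supported so that evidence on partial attitude
#'   change can be expressed. `NULL` (default) computes both scenarios.
#' * `rounding` — per-country rounding of unrounded estimates:
#'   `"half-away"` (half away from zero, default) or `"half-even"`
#'   (banker's rounding).
#' * `type_split_undergone` — `"complement"` (default): type III is rounded
#'   from the unrounded base and the other-types cell is the complement from
#'   the rounded total, so the pair sums to the total exactly;
#'   `"independent"` rounds both cells from the unrounded base.
#' * `type_split_risk` — same choice for the at-risk type split; default
#'   `"independent"` (cells may differ from the rounded scenario total by
#'   one).
#' * `include_g1x_in_population`, `include_excluded_in_population` — whether
#'   the residual first-generation bucket and excluded records count in the
#'   denominator population used for national shares (defaults `TRUE` /
#'   `FALSE`).
#'
#' @param reference_date Reference date (`Date` or `"YYYY-MM-DD"`).
#' @param acculturation_factor_gen2 `NULL`, or a number in `[0, 1]`.
#' @param rounding `"half-away"` or `"half-even"`.
#' @param type_split_undergone,type_split_risk `"complement"` or
#'   `"independent"`.
#' @param include_g1x_in_population,include_excluded_in_population Logicals.
#' @return A list of class `fgmc_scenario_config`.
#' @export
scenario_config <- function(reference_date = as.Date("2013-01-01"),
                            acculturation_factor_gen2 = NULL,
                            rounding = c("half-away", "half-even"),
                            type_split_undergone = c("complement", "independent"),
                            type_split_risk = c("independent", "complement"),
                            include_g1x_in_population = TRUE,
                            include_excluded_in_population = FALSE) {
  if (!is.null(acculturation_factor_gen2)) {
    f <- acculturation_factor_gen2
    if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0 || f > 1) {
      stop_fgmc("acculturation_factor_gen2 must be a single number in [0, 1]")
    }
  }
  cfg <- list(
    reference_date = as.Date(reference_date),
    acculturation_factor_gen2 = acculturation_factor_gen2,
    rounding = match.arg(rounding),
    type_split_undergone = match.arg(type_split_undergone),
    type_split_risk = match.arg(type_split_risk),
    include_g1x_in_population = include_g1x_in_population,
    include_excluded_in_population = include_excluded_in_population
  )
  structure(cfg, class = "fgmc_scenario_config")
}

as_scenario_config <- function(cfg) {
  if (inherits(cfg, "fgmc_scenario_config")) cfg else do.call(scenario_config, cfg)
}

# join profile columns onto a per-country table, erroring when a country
# with relevant nonzero counts has no profile
join_profiles <- function(tbl, profiles, needed_cols, relevant) {
  idx <- match(norm_country(tbl$country), norm_country(profiles$country))
  missing <- is.na(idx) & relevant
  if (any(missing)) {
    stop_fgmc(
      "no profile for country with nonzero counts: ",
      paste(tbl$country[missing], collapse = ", ")
    )
  }
  for (col in needed_cols) tbl[[col]] <- profiles[[col]][idx]
  tbl
}

require_cells <- function(counts, cols, what) {
  bad <- rowSums(is.na(counts[cols])) > 0
  if (any(bad)) {
    stop_fgmc(
      what, " needs complete ", paste(cols, collapse = "+"),
      " counts; suppressed (NA) cells present for: ",
      paste(counts$country[bad], collapse = ", "),
      ". Complete the table or use impute_suppressed()."
    )
  }
}

#' Estimate women and girls already subjected to FGM/C
#'
#' Women and girls who arrived older than the customary cutting-age window
#' of their origin country (cohort 1a) are assumed to have been subjected to
#' FGM/C before migration in the same proportion as the 15-49 prevalence in
#' that country; cutting after migration is assumed not to occur. Per
#' country:
#' \deqn{U_c = N_{1a,c} \times p^{15\textrm{-}49}_c}
#' rounded per the configured rounding mode; the national total is the sum
#' of rounded per-country values.
#'
#' @param counts An `fgmc_group_counts` tibble (microdata tabulation or
#'   aggregate input).
#' @param profiles An `fgmc_profiles` tibble.
#' @param cfg An [scenario_config()] object.
#' @return Tibble with `country`, `g1a`, `undergone_unrounded`, `undergone`.
#' @examples
#' profiles <- load_profiles()
#' counts <- group_counts(tibble::tibble(
#'   country = "Somalia", g1a = 8873, g1b = 1630, g1c = 593,
#'   g2a = 3654, g2b = 206
#' ))
#' estimate_undergone(counts, profiles)$undergone # 8687
#' @export
estimate_undergone <- function(counts, profiles, cfg = scenario_config()) {
  cfg <- as_scenario_config(cfg)
  require_cells(counts, "g1a", "estimate_undergone()")
  tbl <- tibble::as_tibble(counts)[, c("country", "g1a")]
  tbl <- join_profiles(tbl, profiles, "prev_15_49", relevant = tbl$g1a > 0)
  tbl |>
    dplyr::mutate(
      undergone_unrounded = .data$g1a * dplyr::coalesce(.data$prev_15_49, 0),
      undergone = fgmc_round(.data$undergone_unrounded, cfg$rounding)
    ) |>
    dplyr::select("country", "g1a", "undergone_unrounded", "undergone")
}

#' Split the undergone estimate into type III and other types
#'
#' Extrapolates the origin-country 15-49 type-III (infibulation) share to
#' the per-country undergone estimate. Under the default complement
#' convention, type III is rounded from the unrounded base and other types
#' is the rounded total minus type III, so the pair always sums to the
#' rounded undergone total.
#'
#' @param undergone Output of [estimate_undergone()].
#' @inheritParams estimate_undergone
#' @return `undergone` with `undergone_type3`, `undergone_other` and the
#'   `type3_assumed_zero` flag added.
#' @export
split_undergone_types <- function(undergone, profiles, cfg = scenario_config()) {
  cfg <- as_scenario_config(cfg)
  tbl <- join_profiles(undergone, profiles, c("type3_15_49", "type3_assumed_zero"),
    relevant = undergone$g1a > 0
  )
  tbl <- dplyr::mutate(tbl,
    undergone_type3 = fgmc_round(
      .data$undergone_unrounded * dplyr::coalesce(.data$type3_15_49, 0),
      cfg$rounding
    )
  )
  if (cfg$type_split_undergone == "complement") {
    tbl <- dplyr::mutate(tbl, undergone_other = .data$undergone - .data$undergone_type3)
  } else {
    tbl <- dplyr::mutate(tbl,
      undergone_other = fgmc_round(
        .data$undergone_unrounded * (1 - dplyr::coalesce(.data$type3_15_49, 0)),
        cfg$rounding
      )
    )
  }
  dplyr::select(
    tbl, "country", "g1a", "undergone_unrounded", "undergone",
    "undergone_type3", "undergone_other", "type3_assumed_zero"
  )
}

#' Girls potentially at risk of FGM/C
#'
#' Girls potentially at risk are the target of universal preventive
#' measures: first-generation girls who arrived younger than or within the
#' customary window and are still under 18 (cohorts 1b and 1c) plus
#' second-generation girls under 18 (cohort 2a). No prevalence adjustment is
#' applied.
#'
#' @inheritParams estimate_undergone
#' @return Tibble with `country`, `g1b`, `g1c`, `g2a`,
#'   `potentially_at_risk`.
#' @export
potentially_at_risk <- function(counts) {
  require_cells(counts, c("g1b", "g1c", "g2a"), "potentially_at_risk()")
  tibble::as_tibble(counts)[, c("country", "g1b", "g1c", "g2a")] |>
    dplyr::mutate(
      potentially_at_risk = .data$g1b + .data$g1c + .data$g2a
    )
}

#' Estimate girls at risk of FGM/C under migration scenarios
#'
#' The risk model multiplies the at-risk base by the origin country's 15-19
#' prevalence. With the migration and acculturation impact factor `f` for
#' the second generation:
#' \deqn{R_c(f) = \left(N_{1b,c} + N_{1c,c} + (1-f)\,N_{2a,c}\right)
#'   \times p^{15\textrm{-}19}_c}
#' The low-risk scenario sets `f = 1` (only the first-generation cohorts 1b
#' and 1c contribute), the high-risk scenario `f = 0` (cohort 2a contributes
#' fully). First-generation girls who arrived older than the window, and
#' anyone 18+ at the reference date, are outside the risk base by
#' construction of the cohorts.
#'
#' @inheritParams estimate_undergone
#' @param scenario `"both"` (default), `"low"`, or `"high"`. When
#'   `cfg$acculturation_factor_gen2` is set, that single factor is used
#'   instead and one scenario column `risk` is returned.
#' @return Tibble with per-country unrounded and rounded risk estimates:
#'   `risk_low_unrounded`, `risk_low`, `risk_high_unrounded`, `risk_high`
#'   (or `risk_unrounded`/`risk` for a single factor). The unrounded values
#'   feed the type split.
#' @examples
#' profiles <- load_profiles()
#' counts <- group_counts(tibble::tibble(
#'   country = "Somalia", g1a = 8873, g1b = 1630, g1c = 593,
#'   g2a = 3654, g2b = 206
#' ))
#' estimate_risk(counts, profiles)[, c("risk_low", "risk_high")] # 2150, 5683
#' @export
estimate_risk <- function(counts, profiles, cfg = scenario_config(),
                          scenario = c("both", "low", "high")) {
  cfg <- as_scenario_config(cfg)
  scenario <- match.arg(scenario)
  require_cells(counts, c("g1b", "g1c", "g2a"), "estimate_risk()")
  tbl <- tibble::as_tibble(counts)[, c("country", "g1b", "g1c", "g2a")]
  relevant <- (tbl$g1b + tbl$g1c + tbl$g2a) > 0
  tbl <- join_profiles(tbl, profiles, "prev_15_19", relevant = relevant)
  p19 <- dplyr::coalesce(tbl$prev_15_19, 0)
  risk_at <- function(f) (tbl$g1b + tbl$g1c + (1 - f) * tbl$g2a) * p19

  if (!is.null(cfg$acculturation_factor_gen2)) {
    u <- risk_at(cfg$acculturation_factor_gen2)
    out <- dplyr::mutate(tbl,
      risk_unrounded = u, risk = fgmc_round(u, cfg$rounding)
    )
    return(dplyr::select(out, -"prev_15_19"))
  }

  out <- tbl
  if (scenario %in% c("both", "low")) {
    out$risk_low_unrounded <- risk_at(1)
    out$risk_low <- fgmc_round(out$risk_low_unrounded, cfg$rounding)
  }
  if (scenario %in% c("both", "high")) {
    out$risk_high_unrounded <- risk_at(0)
    out$risk_high <- fgmc_round(out$risk_high_unrounded, cfg$rounding)
  }
  dplyr::select(out, -"prev_15_19")
}

#' Split at-risk estimates into type III and other types
#'
#' Extrapolates the origin-country 15-19 type-III share to each risk
#' scenario. Under the default independent convention both cells are rounded
#' from the unrounded scenario base, so the pair may differ from the rounded
#' scenario total by one.
#'
#' @param risk Output of [estimate_risk()] (unrounded columns retained).
#' @inheritParams estimate_undergone
#' @return `risk` with `<scenario>_type3` and `<scenario>_other` columns
#'   added for each scenario present.
#' @export
split_risk_types <- function(risk, profiles, cfg = scenario_config()) {
  cfg <- as_scenario_config(cfg)
  u_cols <- grep("_unrounded$", names(risk), value = TRUE)
  if (length(u_cols) == 0) {
    stop_fgmc("split_risk_types() needs the unrounded risk columns")
  }
  relevant <- Reduce(`|`, lapply(u_cols, function(cl) risk[[cl]] > 0))
  tbl <- join_profiles(risk, profiles, "type3_15_19", relevant = relevant)
  s <- dplyr::coalesce(tbl$type3_15_19, 0)
  for (u_col in u_cols) {
    base_name <- sub("_unrounded$", "", u_col)
    u <- tbl[[u_col]]
    type3 <- fgmc_round(u * s, cfg$rounding)
    other <- if (cfg$type_split_risk == "independent") {
      fgmc_round(u * (1 - s), cfg$rounding)
    } else {
      tbl[[base_name]] - type3
    }
    tbl[[paste0(base_name, "_type3")]] <- type3
    tbl[[paste0(base_name, "_other")]] <- other
  }
  dplyr::select(tbl, -"type3_15_19")
}

#' Run the full extrapolation estimator
#'
#' Convenience wrapper producing every headline quantity from a cohort count
#' table: per-country undergone estimates with type-III split, potentially
#' at risk, low/high risk scenarios with type-III splits, and the national
#' summary.
#'
#' @inheritParams estimate_undergone
#' @return An object of class `fgmc_estimates`: a list with `countries` (the
#'   wide per-country estimate tibble), `summary` (one-row national summary,
#'   see [national_summary()]), `counts` and `cfg`. Supports
#'   [broom::tidy()], [broom::glance()], [ggplot2::autoplot()] and
#'   `print()`.
#' @examples
#' profiles <- load_profiles()
#' counts <- read_group_counts(
#'   system.file("extdata", "group_counts_completed_synthetic.csv",
#'     package = "fgmcprev"
#'   )
#' )
#' est <- fgmc_estimate(counts, profiles)
#' est
#' @export
fgmc_estimate <- function(counts, profiles, cfg = scenario_config()) {
  cfg <- as_scenario_config(cfg)
  undergone <- estimate_undergone(counts, profiles, cfg)
  undergone <- split_undergone_types(undergone, profiles, cfg)
  par <- potentially_at_risk(counts)
  risk <- estimate_risk(counts, profiles, cfg)
  risk <- split_risk_types(risk, profiles, cfg)

  countries <- tibble::as_tibble(counts)[
    , c("country", count_cols, "total")
  ] |>
    dplyr::left_join(undergone[, setdiff(names(undergone), "g1a")],
      by = "country"
    ) |>
    dplyr::left_join(
      par[, c("country", "potentially_at_risk")],
      by = "country"
    ) |>
    dplyr::left_join(
      risk[, setdiff(names(risk), c("g1b", "g1c", "g2a"))],
      by = "country"
    )

  out <- structure(
    list(countries = countries, counts = counts, cfg = cfg),
    class = "fgmc_estimates"
  )
  out$summary <- national_summary(out)
  out
}

#' National summary of the extrapolation estimates
#'
#' National totals are sums of rounded per-country values. Shares are
#' proportions: the undergone share uses the total resident population
#' originating from the listed countries as denominator (including the
#' residual `1x` cohort by default, excluding records attributed to no
#' listed country), the type-III shares use the respective totals.
#'
#' @param est An `fgmc_estimates` object.
#' @return A one-row tibble with `population`, `undergone_total`,
#'   `undergone_share`, `undergone_type3_total`, `type3_share_of_undergone`,
#'   `potentially_at_risk_total`, `risk_low_total`, `risk_high_total`,
#'   per-scenario type-III totals and shares. Shares are proportions;
#'   `print()` renders them as one-decimal percentages.
#' @export
national_summary <- function(est) {
  stopifnot(inherits(est, "fgmc_estimates"))
  ct <- est$countries
  cfg <- est$cfg
  population <- sum(ct$total, na.rm = TRUE)
  if (!cfg$include_g1x_in_population) {
    population <- population - sum(ct$g1x, na.rm = TRUE)
  }
  if (cfg$include_excluded_in_population) {
    population <- population + (attr(est$counts, "excluded") %||% 0L)
  }
  tot <- function(col) {
    if (col %in% names(ct)) sum(ct[[col]], na.rm = TRUE) else NA_real_
  }
  undergone_total <- tot("undergone")
  type3_total <- tot("undergone_type3")
  risk_low_total <- tot("risk_low")
  risk_high_total <- tot("risk_high")
  share <- function(num, den) if (!is.na(den) && den > 0) num / den else 0
  tibble::tibble(
    population = population,
    undergone_total = undergone_total,
    undergone_share = share(undergone_total, population),
    undergone_type3_total = type3_total,
    type3_share_of_undergone = share(type3_total, undergone_total),
    potentially_at_risk_total = tot("potentially_at_risk"),
    risk_low_total = risk_low_total,
    risk_high_total = risk_high_total,
    risk_low_type3_total = tot("risk_low_type3"),
    risk_high_type3_total = tot("risk_high_type3"),
    type3_share_of_risk_low = share(tot("risk_low_type3"), risk_low_total),
    type3_share_of_risk_high = share(tot("risk_high_type3"), risk_high_total)
  )
}

#' @export
print.fgmc_estimates <- function(x, ...) {
  s <- x$summary
  cat("FGM/C extrapolation estimates (", nrow(x$countries), " countries, ",
    "reference date ", format(x$cfg$reference_date), ")\n",
    sep = ""
  )
  cat("  population:           ", s$population, "\n", sep = "")
  cat("  undergone FGM/C:      ", s$undergone_total,
    " (", fmt_percent(s$undergone_share), " of population)\n",
    sep = ""
  )
  cat("  of which type III:    ", s$undergone_type3_total,
    " (", fmt_percent(s$type3_share_of_undergone), ")\n",
    sep = ""
  )
  cat("  potentially at risk:  ", s$potentially_at_risk_total, "\n", sep = "")
  cat("  at risk (low-high):   ", s$risk_low_total, " - ", s$risk_high_total,
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy an estimates object into a long per-country table
#'
#' @param x An `fgmc_estimates` object.
#' @param ... Unused.
#' @return A long tibble with `country`, `quantity`, `value`.
#' @method tidy fgmc_estimates
#' @export
tidy.fgmc_estimates <- function(x, ...) {
  x$countries |>
    tidyr::pivot_longer(-"country",
      names_to = "quantity", values_to = "value"
    )
}

#' One-row national summary (broom interface)
#'
#' @inheritParams tidy.fgmc_estimates
#' @return The [national_summary()] tibble.
#' @method glance fgmc_estimates
#' @export
glance.fgmc_estimates <- function(x, ...) {
  x$summary
}
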