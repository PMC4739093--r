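#' Run the full estimation pipeline and write disclosure-safe reports
#'
#' Orchestrates the whole analysis: resolve the input population (register
#' microdata, an aggregate cohort-count table, or a generator spec),
#' classify and tabulate, estimate every headline quantity, apply
#' statistical-disclosure control, and write the output tables plus a
#' machine-readable run manifest to `out_dir`.
#'
#' Exactly one of `register`, `counts`, `generator_counts` must be given:
#'
#' * `register` — a register tibble or the path of a register file.
#' * `counts` — an `fgmc_group_counts` tibble or the path of an aggregate
#'   counts file (the route for reproducing published tables without
#'   microdata).
#' * `generator_counts` — marginals handed to [generate_register()]
#'   (end-to-end synthetic run; uses `seed`).
#'
#' Written files: `group_counts.csv`, `undergone.csv`,
#' `undergone_types.csv`, `potentially_at_risk.csv`, `risk_scenarios.csv`,
#' `risk_types.csv`, `national_summary.csv`, `manifest.json`. Any stage
#' error is propagated with the stage name and partial outputs are removed.
#'
#' @param register,counts,generator_counts The input population (see
#'   above).
#' @param profiles An `fgmc_profiles` tibble or a profiles file path.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [scenario_config()].
#' @param disclosure A [disclosure_config()].
#' @param seed Seed for the generator route.
#' @return Invisibly, a list with the `fgmc_estimates` object, the counts
#'   table and the written file paths.
#' @export
run_pipeline <- function(register = NULL, counts = NULL, generator_counts = NULL,
                         profiles = load_profiles(), out_dir,
                         cfg = scenario_config(),
                         disclosure = disclosure_config(), seed = 1L) {
  inputs <- c(
    register = !is.null(register), counts = !is.null(counts),
    generator = !is.null(generator_counts)
  )
  if (sum(inputs) != 1) {
    stop_fgmc(
      "[configuration] give exactly one of register, counts, generator_counts"
    )
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_fgmc("[", name, "] ", conditionMessage(e))
    })
  }

  input_digests <- list()
  profiles <- stage("profiles", {
    if (is.character(profiles)) {
      input_digests$profiles <- unname(tools::md5sum(profiles))
      load_profiles(profiles)
    } else {
      profiles
    }
  })

  counts <- stage("input", {
    if (!is.null(register)) {
      if (is.character(register)) {
        input_digests$register <- unname(tools::md5sum(register))
        register <- read_register(register)
      }
      tabulate_groups(register, profiles, cfg$reference_date)
    } else if (!is.null(counts)) {
      if (is.character(counts)) {
        input_digests$counts <- unname(tools::md5sum(counts))
        counts <- read_group_counts(counts)
      }
      counts
    } else {
      reg <- generate_register(generator_counts, profiles,
        reference_date = cfg$reference_date, seed = seed
      )
      tabulate_groups(reg, profiles, cfg$reference_date)
    }
  })

  est <- stage("estimate", fgmc_estimate(counts, profiles, cfg))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail_cleanup <- function(e) {
    unlink(written)
    stop_fgmc("[report] ", conditionMessage(e))
  }

  tryCatch(
    {
      emit <- function(tbl, name, cols) {
        pooled <- pool_small_countries(tbl, disclosure,
          totals = est$countries$total
        )
        report <- render_report(pooled, disclosure, cols = cols)
        path <- file.path(out_dir, name)
        readr::write_delim(report, path, delim = ";", na = "")
        written <<- c(written, path)
        path
      }
      ct <- est$countries
      emit(ct, "group_counts.csv", c(count_cols, "total"))
      emit(ct, "undergone.csv", c("g1a", "undergone"))
      emit(
        ct, "undergone_types.csv",
        c("undergone_type3", "undergone_other", "undergone")
      )
      emit(
        ct, "potentially_at_risk.csv",
        c("g1b", "g1c", "g2a", "potentially_at_risk")
      )
      emit(ct, "risk_scenarios.csv", c("risk_low", "risk_high"))
      emit(
        ct, "risk_types.csv",
        c("risk_low_type3", "risk_low_other", "risk_high_type3", "risk_high_other")
      )

      summary_path <- file.path(out_dir, "national_summary.csv")
      readr::write_delim(est$summary, summary_path, delim = ";")
      written <- c(written, summary_path)

      manifest <- list(
        package = "fgmcprev",
        version = as.character(utils::packageVersion("fgmcprev")),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed,
        input_mode = names(inputs)[inputs],
        input_digests = input_digests,
        n_countries = nrow(est$countries),
        population = est$summary$population,
        excluded_records = attr(counts, "excluded") %||% 0L,
        scenario_config = list(
          reference_date = format(cfg$reference_date),
          acculturation_factor_gen2 = cfg$acculturation_factor_gen2,
          rounding = cfg$rounding,
          type_split_undergone = cfg$type_split_undergone,
          type_split_risk = cfg$type_split_risk
        ),
        disclosure_config = list(
          suppress_low = disclosure$suppress_low,
          suppress_high = disclosure$suppress_high,
          pool_threshold = disclosure$pool_threshold,
          pooled_label = disclosure$pooled_label,
          marker = disclosure$marker
        ),
        files = basename(written)
      )
      manifest_path <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path,
        auto_unbox = TRUE, pretty = TRUE, null = "null"
      )
      written <- c(written, manifest_path)
    },
    error = on_fail_cleanup
  )

  invisible(list(estimates = est, counts = counts, files = written))
}
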