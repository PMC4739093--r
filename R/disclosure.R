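#' Statistical-disclosure configuration
#'
#' Small-cell suppression and small-country pooling settings used when
#' publishing register-derived tables: counts in the band
#' `[suppress_low, suppress_high]` (default 1-9, i.e. "more than 0 and less
#' than 10") are replaced by a marker, and countries whose total resident
#' count is below `pool_threshold` (default 20) are pooled into one
#' aggregate row.
#'
#' @param suppress_low,suppress_high Inclusive bounds of the suppressed
#'   band.
#' @param pool_threshold Countries with total residents strictly below this
#'   are pooled.
#' @param pooled_label Row label for the pooled countries.
#' @param marker String rendered in place of suppressed cells.
#' @return A list of class `fgmc_disclosure_config`.
#' @export
disclosure_config <- function(suppress_low = 1L, suppress_high = 9L,
                              pool_threshold = 20L,
                              pooled_label = "Other countries",
                              marker = "<10") {
  if (!(suppress_low > 0 && suppress_low <= suppress_high &&
    suppress_high < pool_threshold)) {
    stop_fgmc("need 0 < suppress_low <= suppress_high < pool_threshold")
  }
  structure(
    list(
      suppress_low = as.integer(suppress_low),
      suppress_high = as.integer(suppress_high),
      pool_threshold = as.integer(pool_threshold),
      pooled_label = pooled_label,
      marker = marker
    ),
    class = "fgmc_disclosure_config"
  )
}

#' Pool small countries into one aggregate row
#'
#' Rows whose reference total is strictly below the pooling threshold are
#' summed (numeric columns only) into a single row labelled
#' `cfg$pooled_label`, placed last. Pooling protects against disclosure of
#' very small national groups while keeping their contribution in the
#' totals. When the table holds per-country estimates, pass the resident
#' totals via `totals` so that membership is decided on population size, not
#' on the estimate: each constituent country is then estimated with its own
#' prevalence and the pooled row is the sum of those estimates.
#'
#' @param table Data frame with a `country` column and numeric columns.
#' @param cfg A [disclosure_config()].
#' @param totals Numeric vector (aligned with `table` rows) used to decide
#'   membership; defaults to `table$total`.
#' @return The table with small rows replaced by one pooled row (attribute
#'   `pooled_members` lists them); unchanged when no row is below the
#'   threshold.
#' @export
pool_small_countries <- function(table, cfg = disclosure_config(),
                                 totals = table$total) {
  if (is.null(totals)) {
    stop_fgmc("pool_small_countries() needs reference totals")
  }
  small <- !is.na(totals) & totals < cfg$pool_threshold
  if (!any(small)) {
    return(table)
  }
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  pooled <- table[1, , drop = FALSE]
  pooled$country <- cfg$pooled_label
  for (col in names(table)) {
    if (col %in% num_cols) {
      pooled[[col]] <- sum(table[[col]][small])
    } else if (col != "country") {
      pooled[[col]] <- NA
    }
  }
  out <- dplyr::bind_rows(table[!small, , drop = FALSE], pooled)
  attr(out, "pooled_members") <- table$country[small]
  attr(out, "excluded") <- attr(table, "excluded")
  if (inherits(table, "fgmc_group_counts")) {
    class(out) <- class(table)
  }
  out
}

#' Suppress small cells in a published table
#'
#' Replaces every integer cell `v` with `suppress_low <= v <= suppress_high`
#' by the disclosure marker. Zero is information-free here and stays
#' rendered as `0`; values above the band are rendered as printed integers.
#' The operation returns character columns and is idempotent.
#'
#' @param table Data frame; `cols` default to all numeric columns.
#' @param cfg A [disclosure_config()].
#' @param cols Columns to process.
#' @return A tibble whose processed columns are character: integers, `"0"`,
#'   or the marker.
#' @export
suppress_cells <- function(table, cfg = disclosure_config(), cols = NULL) {
  cols <- cols %||% names(table)[vapply(table, is.numeric, logical(1))]
  out <- tibble::as_tibble(table)
  for (col in cols) {
    v <- out[[col]]
    if (is.character(v)) next # already rendered: idempotent
    rendered <- ifelse(is.na(v), cfg$marker, format(v, scientific = FALSE, trim = TRUE))
    band <- !is.na(v) & v >= cfg$suppress_low & v <= cfg$suppress_high
    rendered[band] <- cfg$marker
    out[[col]] <- rendered
  }
  out
}

#' Render a disclosure-safe report table
#'
#' Orders country rows alphabetically with the pooled row last, appends a
#' total row computed **before** suppression (published totals include the
#' suppressed cells, so visible cells need not sum to the printed total),
#' then applies small-cell suppression.
#'
#' @param table Per-country data frame (counts or estimates) with a
#'   `country` column.
#' @param cfg A [disclosure_config()].
#' @param cols Columns to render; default all numeric.
#' @param total_label Label of the totals row.
#' @return A tibble of class `fgmc_report` with character cells.
#' @export
render_report <- function(table, cfg = disclosure_config(), cols = NULL,
                          total_label = "Total") {
  cols <- cols %||% names(table)[vapply(table, is.numeric, logical(1))]
  tbl <- tibble::as_tibble(table)[, c("country", cols)]
  pooled <- tbl$country == cfg$pooled_label
  tbl <- dplyr::bind_rows(
    dplyr::arrange(tbl[!pooled, ], .data$country),
    tbl[pooled, ]
  )
  totals <- tbl[1, , drop = FALSE]
  totals$country <- total_label
  for (col in cols) totals[[col]] <- sum(tbl[[col]], na.rm = TRUE)
  out <- suppress_cells(dplyr::bind_rows(tbl, totals), cfg, cols)
  class(out) <- c("fgmc_report", class(out))
  out
}

#' Parse a rendered report back to numbers
#'
#' Inverse of [render_report()] up to suppression: marker cells become `NA`,
#' all other cells are restored as integers.
#'
#' @param report An `fgmc_report` tibble (or a data frame read back from a
#'   rendered file).
#' @param cfg The [disclosure_config()] used to render.
#' @return A tibble with integer columns (`NA` = suppressed).
#' @export
parse_report <- function(report, cfg = disclosure_config()) {
  out <- tibble::as_tibble(report)
  for (col in setdiff(names(out), "country")) {
    v <- as.character(out[[col]])
    v[v == cfg$marker] <- NA
    out[[col]] <- as.integer(v)
  }
  class(out) <- setdiff(class(out), "fgmc_report")
  out
}
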