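#' Age in completed years at a date
#'
#' Birthday-based age: the age increments on the anniversary of the birth
#' date, and the anniversary itself counts as attained. A person born on a
#' 29 February attains their birthday on 1 March in non-leap years.
#'
#' @param birth_date,at_date `Date` vectors (recycled to common length).
#' @return Integer vector of whole years elapsed.
#' @examples
#' age_on(as.Date("2004-05-01"), as.Date("2013-01-01")) # 8
#' age_on(as.Date("2004-05-01"), as.Date("2012-05-01")) # 8: anniversary attained
#' @export
age_on <- function(birth_date, at_date) {
  birth_date <- as.Date(birth_date)
  at_date <- as.Date(at_date)
  n <- max(length(birth_date), length(at_date))
  birth_date <- rep_len(birth_date, n)
  at_date <- rep_len(at_date, n)
  if (any(at_date < birth_date, na.rm = TRUE)) {
    stop_fgmc("age_on(): at_date precedes birth_date")
  }
  bl <- as.POSIXlt(birth_date)
  al <- as.POSIXlt(at_date)
  years <- al$year - bl$year
  before_anniversary <- (al$mon < bl$mon) |
    (al$mon == bl$mon & al$mday < bl$mday)
  as.integer(years - before_anniversary)
}

group_levels <- c("1a", "1b", "1c", "1x", "2a", "2b", "excluded")

#' Attribute each register record to an origin country
#'
#' First-generation records are attributed to their own country of birth if
#' it is listed in the profile set. Second-generation records are attributed
#' only when BOTH parents' countries are listed; where the two parents come
#' from two different listed countries, the mother's country of birth is
#' used. Records with an unlisted country of birth, or with one or neither
#' parent from a listed country, get `NA`: they are excluded from all
#' estimation, since risk is very uncertain and most likely low with only
#' one practising-country parent.
#'
#' @param records Register tibble (see [read_register()] for the layout).
#' @param profiles An `fgmc_profiles` tibble.
#' @return `records` with an `attributed_country` character column added
#'   (profile spelling; `NA` = excluded).
#' @export
attributed_country <- function(records, profiles) {
  key <- norm_country(profiles$country)
  lookup <- function(x) {
    idx <- match(norm_country(x), key)
    profiles$country[idx]
  }
  gen <- records$generation
  own <- lookup(records$country_of_birth)
  mother <- lookup(records$mother_country)
  father <- lookup(records$father_country)
  attributed <- as.character(ifelse(gen == 1L, own,
    ifelse(!is.na(mother) & !is.na(father), mother, NA_character_)
  ))
  dplyr::mutate(records, attributed_country = attributed)
}

#' Classify register records into analysis cohorts
#'
#' Assigns every record exactly one cohort label using generation, age at
#' arrival, age at the reference date, and the attributed country's
#' customary cutting-age window `[cut_age_min, cut_age_max]`:
#'
#' * `"1a"` first generation, arrived *older than* the window
#'   (`age_at_arrival > cut_age_max`); assumed already subjected in
#'   proportion to the origin country's 15-49 prevalence.
#' * `"1b"` first generation, arrived younger than or within the window,
#'   now past it but under 18.
#' * `"1c"` first generation, arrived younger than or within the window and
#'   still within it or younger.
#' * `"1x"` first generation, arrived younger than or within the window but
#'   18 or older at the reference date (residual bucket: assumed not
#'   subjected, and past the at-risk age).
#' * `"2a"` second generation under 18; `"2b"` second generation 18+.
#' * `"excluded"` records with no attributable listed country.
#'
#' The upper margin of the customary age is used as the cut-off: "older
#' than" is strict (`> cut_age_max`), "younger than or within" is
#' `<= cut_age_max`, and "under 18" is `< 18` in completed years (a person
#' whose 18th birthday has been attained is out).
#'
#' @param records Register tibble.
#' @param profiles An `fgmc_profiles` tibble.
#' @param reference_date Analysis reference date (`Date`).
#' @param age_mode `"birthday"` (default; completed years, birthday-based) or
#'   `"calendar_year"` (age = reference year minus birth year, the
#'   convention of some register statistics).
#' @return `records` with `attributed_country` and a `group` factor column
#'   (levels `"1a"`, `"1b"`, `"1c"`, `"1x"`, `"2a"`, `"2b"`, `"excluded"`).
#' @export
classify_records <- function(records, profiles,
                             reference_date = as.Date("2013-01-01"),
                             age_mode = c("birthday", "calendar_year")) {
  age_mode <- match.arg(age_mode)
  reference_date <- as.Date(reference_date)
  if (!all(records$generation %in% c(1L, 2L))) {
    stop_fgmc("generation must be 1 or 2")
  }
  if (anyNA(records$arrival_date[records$generation == 1L])) {
    stop_fgmc("first-generation record with missing arrival_date")
  }

  records <- attributed_country(records, profiles)
  win <- profiles[, c("country", "cut_age_max")]
  records <- dplyr::left_join(records, win,
    by = c(attributed_country = "country")
  )

  age_at <- function(birth, at) {
    if (age_mode == "birthday") {
      age_on(birth, at)
    } else {
      as.integer(format(at, "%Y")) - as.integer(format(birth, "%Y"))
    }
  }
  a_ref <- age_at(records$birth_date, reference_date)
  gen1 <- records$generation == 1L & !is.na(records$attributed_country)
  a_arr <- rep(NA_integer_, nrow(records))
  if (any(gen1)) {
    a_arr[gen1] <- age_at(records$birth_date[gen1], records$arrival_date[gen1])
  }

  m <- records$cut_age_max
  group <- rep("excluded", nrow(records))
  g1 <- gen1
  group[g1 & a_arr > m] <- "1a"
  group[g1 & a_arr <= m & a_ref <= m] <- "1c"
  group[g1 & a_arr <= m & a_ref > m & a_ref < 18L] <- "1b"
  group[g1 & a_arr <= m & a_ref >= 18L & a_ref > m] <- "1x"
  gen2 <- records$generation == 2L & !is.na(records$attributed_country)
  group[gen2 & a_ref < 18L] <- "2a"
  group[gen2 & a_ref >= 18L] <- "2b"

  records$cut_age_max <- NULL
  dplyr::mutate(records, group = factor(group, levels = group_levels))
}

#' Tabulate per-country cohort counts
#'
#' Counts every record once under its attributed country and cohort label.
#' Excluded records (no attributable listed country) are counted in a
#' separate bucket carried as the `"excluded"` attribute, not under any
#' country row.
#'
#' @inheritParams classify_records
#' @param fold_g1x Fold the `1x` residual cohort into `1a` for table-shape
#'   compatibility with five-group count tables? Default `FALSE`: the `1x`
#'   bucket is kept separate because it belongs in neither the undergone
#'   numerator (its members arrived young and are assumed not subjected) nor
#'   the at-risk groups (they are 18+).
#' @return An `fgmc_group_counts` tibble with columns `country`, `g1a`,
#'   `g1b`, `g1c`, `g1x`, `g2a`, `g2b`, `total`, one row per country with at
#'   least one record, plus attribute `excluded` (count of excluded
#'   records).
#' @export
tabulate_groups <- function(records, profiles,
                            reference_date = as.Date("2013-01-01"),
                            age_mode = c("birthday", "calendar_year"),
                            fold_g1x = FALSE) {
  classified <- classify_records(records, profiles, reference_date, age_mode)
  excluded_n <- sum(classified$group == "excluded")
  kept <- dplyr::filter(classified, .data$group != "excluded")
  counts <- kept |>
    dplyr::count(.data$attributed_country, .data$group) |>
    tidyr::pivot_wider(
      names_from = "group", values_from = "n", values_fill = 0L,
      names_expand = TRUE
    ) |>
    dplyr::rename(country = "attributed_country") |>
    dplyr::select(-dplyr::any_of("excluded")) |>
    dplyr::rename_with(~ paste0("g", .x), -"country") |>
    dplyr::arrange(.data$country)
  if (fold_g1x) {
    counts <- dplyr::mutate(counts, g1a = .data$g1a + .data$g1x, g1x = 0L)
  }
  counts <- dplyr::mutate(counts,
    dplyr::across(dplyr::starts_with("g"), as.integer),
    total = .data$g1a + .data$g1b + .data$g1c + .data$g1x +
      .data$g2a + .data$g2b
  )
  new_group_counts(counts, excluded = excluded_n)
}

new_group_counts <- function(counts, excluded = 0L) {
  class(counts) <- c("fgmc_group_counts", class(tibble::tibble()))
  attr(counts, "excluded") <- as.integer(excluded)
  counts
}

count_cols <- c("g1a", "g1b", "g1c", "g1x", "g2a", "g2b")

#' Construct a group-counts table from aggregate data
#'
#' Wraps an aggregate per-country cohort count table (the alternative input
#' path when microdata are not available) into the `fgmc_group_counts`
#' container that the estimators consume. A missing `g1x` column defaults to
#' zero; a missing `total` is recomputed. `NA` cells are allowed and stand
#' for suppressed values.
#'
#' @param df Data frame with a `country` column and integer columns `g1a`,
#'   `g1b`, `g1c`, `g2a`, `g2b` (optionally `g1x`, `total`).
#' @param excluded Count of records excluded from all countries (default 0).
#' @return An `fgmc_group_counts` tibble.
#' @export
group_counts <- function(df, excluded = 0L) {
  if (!"country" %in% names(df)) stop_fgmc("counts need a 'country' column")
  dup <- df$country[duplicated(norm_country(df$country))]
  if (length(dup) > 0) {
    stop_fgmc("duplicate country in counts: ", paste(dup, collapse = ", "))
  }
  if (!"g1x" %in% names(df)) df$g1x <- 0L
  need <- setdiff(count_cols, names(df))
  if (length(need) > 0) {
    stop_fgmc("counts lack required column(s): ", paste(need, collapse = ", "))
  }
  out <- tibble::as_tibble(df)
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(count_cols), as.integer))
  if (any(unlist(out[count_cols]) < 0, na.rm = TRUE)) {
    stop_fgmc("negative cohort count")
  }
  out$total <- rowSums(out[count_cols])
  out <- dplyr::select(
    out, "country", dplyr::all_of(count_cols), "total",
    dplyr::everything()
  )
  new_group_counts(out, excluded = excluded)
}

#' Read / write an aggregate group-counts table
#'
#' The file mirrors published count-table columns: `country`, `g1a`, `g1b`,
#' `g1c`, optionally `g1x`, `g2a`, `g2b`, `total`. Blank cells (or the
#' strings in `suppressed`) are read as `NA`, representing cells withheld by
#' statistical-disclosure control.
#'
#' @param path File path.
#' @param delim Field delimiter, default `";"`.
#' @param suppressed Strings treated as suppressed cells, read as `NA`.
#' @return An `fgmc_group_counts` tibble.
#' @export
read_group_counts <- function(path, delim = ";", suppressed = c("", "<10", ":")) {
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE
  )
  for (col in setdiff(names(raw), "country")) {
    v <- trimws(raw[[col]])
    v[v %in% suppressed] <- NA
    parsed <- suppressWarnings(as.integer(v))
    if (any(!is.na(v) & is.na(parsed))) {
      bad <- which(!is.na(v) & is.na(parsed))[1]
      stop_fgmc(
        "non-integer cell in column '", col, "' at data line ", bad,
        ": '", v[bad], "'"
      )
    }
    raw[[col]] <- parsed
  }
  raw$total <- NULL # recomputed (NA where a row holds suppressed cells)
  group_counts(raw)
}

#' @rdname read_group_counts
#' @param counts An `fgmc_group_counts` tibble.
#' @export
write_group_counts <- function(counts, path, delim = ";") {
  readr::write_delim(
    counts[, c("country", count_cols, "total")], path,
    delim = delim, na = ""
  )
  invisible(path)
}

#' Fill suppressed (NA) cells in a group-counts table
#'
#' Estimation requires complete counts; published tables may carry
#' suppressed small cells as `NA`. This helper imputes a constant (default
#' 0, giving lower-bound estimates) into every `NA` cohort cell and
#' recomputes row totals.
#'
#' @param counts An `fgmc_group_counts` tibble.
#' @param value Integer to place in each suppressed cell.
#' @return An `fgmc_group_counts` tibble with no missing cohort cells.
#' @export
impute_suppressed <- function(counts, value = 0L) {
  for (col in count_cols) {
    counts[[col]][is.na(counts[[col]])] <- as.integer(value)
  }
  counts$total <- rowSums(counts[count_cols])
  counts
}
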