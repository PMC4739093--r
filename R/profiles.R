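#' Path to the packaged country reference table
#'
#' The packaged fixture transcribes, for the 29 countries where FGM/C is
#' concentrated, the national survey prevalences (women 15-49 and girls
#' 15-19), the customary age window for cutting, and the type-III
#' (infibulation) share of each prevalence, as reported in the most recent
#' DHS/MICS country reports.
#'
#' @return Path to the semicolon-delimited reference file.
#' @export
fgmc_profiles_path <- function() {
  system.file("extdata", "fgmc_country_profiles.csv",
    package = "fgmcprev", mustWork = TRUE
  )
}

profile_required_cols <- c(
  "country", "prev_15_49", "prev_15_19", "cut_age_min", "cut_age_max",
  "type3_15_49", "type3_15_19", "source"
)

#' Load and validate country FGM/C profiles
#'
#' Reads a delimiter-separated reference table with one row per country and
#' columns `country`, `prev_15_49`, `prev_15_19`, `cut_age_min`,
#' `cut_age_max`, `type3_15_49`, `type3_15_19`, `source`. Percentages may be
#' written with a decimal comma and a `%` sign (as survey reports print them,
#' e.g. `"97,9 %"`) or as plain decimal proportions; both are normalised to
#' proportions in `[0, 1]`.
#'
#' Countries whose surveys report no typology breakdown may leave the two
#' type-III columns blank; they are assigned a type-III share of 0 and
#' flagged in the `type3_assumed_zero` column, so that downstream estimates
#' treat "no data" as the explicit assumption of zero infibulation rather
#' than as missingness.
#'
#' @param path File to read; defaults to the packaged 29-country table.
#' @param delim Field delimiter, default `";"`.
#' @return A tibble of class `fgmc_profiles` with one validated row per
#'   country: proportions in `[0, 1]`, integer age window with
#'   `0 <= cut_age_min <= cut_age_max <= 18`, and a `type3_assumed_zero`
#'   logical flag. The share of other/undetermined types is the complement
#'   `1 - type3_*` and is not stored.
#' @examples
#' profiles <- load_profiles()
#' dplyr::filter(profiles, country == "Somalia")
#' @export
load_profiles <- function(path = fgmc_profiles_path(), delim = ";") {
  if (!file.exists(path)) {
    stop_fgmc("profiles file does not exist: ", path)
  }
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE
  )
  missing_cols <- setdiff(profile_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop_fgmc("profiles file lacks required column(s): ",
      paste(missing_cols, collapse = ", "))
  }

  dup <- raw$country[duplicated(norm_country(raw$country))]
  if (length(dup) > 0) {
    stop_fgmc("duplicate country in profiles file: ", paste(dup, collapse = ", "))
  }

  profiles <- tibble::tibble(
    country = trimws(raw$country),
    prev_15_49 = parse_percent(raw$prev_15_49),
    prev_15_19 = parse_percent(raw$prev_15_19),
    cut_age_min = suppressWarnings(as.integer(raw$cut_age_min)),
    cut_age_max = suppressWarnings(as.integer(raw$cut_age_max)),
    type3_15_49 = parse_percent(raw$type3_15_49),
    type3_15_19 = parse_percent(raw$type3_15_19),
    type3_assumed_zero = !nzchar(trimws(raw$type3_15_49)) &
      !nzchar(trimws(raw$type3_15_19)),
    source = raw$source
  )
  profiles$type3_15_49[profiles$type3_assumed_zero] <- 0
  profiles$type3_15_19[profiles$type3_assumed_zero] <- 0

  validate_profiles(profiles)
  class(profiles) <- c("fgmc_profiles", class(tibble::tibble()))
  attr(profiles, "provenance") <- paste0(
    "DHS/MICS country reference table, loaded from ", basename(path)
  )
  profiles
}

validate_profiles <- function(profiles) {
  props <- c("prev_15_49", "prev_15_19", "type3_15_49", "type3_15_19")
  for (col in props) {
    v <- profiles[[col]]
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad) > 0) {
      stop_fgmc(
        "proportion out of [0, 1] in column '", col, "' for country: ",
        paste(profiles$country[bad], collapse = ", ")
      )
    }
  }
  bad_age <- which(
    is.na(profiles$cut_age_min) | is.na(profiles$cut_age_max) |
      profiles$cut_age_min < 0 | profiles$cut_age_max < profiles$cut_age_min |
      profiles$cut_age_max > 18
  )
  if (length(bad_age) > 0) {
    stop_fgmc(
      "malformed customary age window (need 0 <= min <= max <= 18) for country: ",
      paste(profiles$country[bad_age], collapse = ", ")
    )
  }
  invisible(profiles)
}

#' Look up one country's profile
#'
#' Exact-match lookup on the normalised (trimmed, case-folded) country name.
#' A country absent from the profile set is a legitimate outcome, not an
#' error: the cohort classifier uses it to exclude records whose origin is
#' not an FGM/C-prevalent country. In that case a zero-row tibble is
#' returned.
#'
#' @param profiles An `fgmc_profiles` tibble from [load_profiles()].
#' @param country Country name (case-insensitive).
#' @return A one-row tibble, or a zero-row tibble when the country is not
#'   listed.
#' @examples
#' profiles <- load_profiles()
#' profile_for(profiles, "somalia")
#' nrow(profile_for(profiles, "Norway")) # 0: not an FGM/C-prevalent country
#' @export
profile_for <- function(profiles, country) {
  stopifnot(length(country) == 1)
  profiles[norm_country(profiles$country) == norm_country(country), ]
}

#' Serialise a profile set back to its file format
#'
#' Writes proportions as plain decimals; countries flagged
#' `type3_assumed_zero` get blank type-III fields so that a load/write/load
#' cycle is the identity on the profile set, flag included.
#'
#' @param profiles An `fgmc_profiles` tibble.
#' @param path Output file.
#' @param delim Field delimiter, default `";"`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, delim = ";") {
  out <- tibble::tibble(
    country = profiles$country,
    prev_15_49 = as.character(profiles$prev_15_49),
    prev_15_19 = as.character(profiles$prev_15_19),
    cut_age_min = profiles$cut_age_min,
    cut_age_max = profiles$cut_age_max,
    type3_15_49 = ifelse(profiles$type3_assumed_zero, "",
      as.character(profiles$type3_15_49)),
    type3_15_19 = ifelse(profiles$type3_assumed_zero, "",
      as.character(profiles$type3_15_19)),
    source = profiles$source
  )
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
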