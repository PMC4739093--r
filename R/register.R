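register_cols <- c(
  "person_id", "birth_date", "generation", "country_of_birth",
  "mother_country", "father_country", "arrival_date"
)

# uniform draw from lo..hi (safe for lo == hi, unlike sample())
sample_int_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# integer age ranges that define each cohort for a window upper bound m at
# the reference date; NULL entry = not applicable
cohort_age_ranges <- function(m, adult_max = 49L) {
  list(
    g1a = list(ref = c(m + 1L, adult_max), arr = "above"), # a_arr in (m, a_ref]
    g1b = if (m + 1L <= 17L) list(ref = c(m + 1L, 17L), arr = "below"),
    g1c = list(ref = c(0L, m), arr = "within"), # a_arr in [0, a_ref]
    g1x = list(ref = c(18L, min(40L, adult_max)), arr = "below"),
    g2a = list(ref = c(0L, 17L), arr = NULL),
    g2b = list(ref = c(18L, adult_max), arr = NULL)
  )
}

# sample one birth date giving completed age a_ref at reference date,
# keeping margin_days away from the interval ends where the width allows
sample_birth_date <- function(reference_date, a_ref, margin_days) {
  b_max <- add_years(reference_date, -a_ref)
  b_min <- add_years(reference_date, -(a_ref + 1L)) + 1L
  lo <- b_min
  hi <- b_max
  while (age_on(lo, reference_date) > a_ref) lo <- lo + 1L
  while (age_on(hi, reference_date) < a_ref) hi <- hi - 1L
  if (as.integer(hi - lo) >= 2L * margin_days + 1L) {
    lo <- lo + margin_days
    hi <- hi - margin_days
  }
  lo + sample.int(as.integer(hi - lo) + 1L, 1L) - 1L
}

# sample one arrival date giving completed age a_arr at arrival, arrival
# strictly before the reference date; NULL if the window is empty.
# Feb-29 births make add_years() roll back a day, so the bounds are nudged
# until the completed age matches exactly.
sample_arrival_date <- function(birth_date, a_arr, reference_date, margin_days) {
  lo <- max(birth_date, add_years(birth_date, a_arr))
  while (age_on(birth_date, lo) < a_arr) lo <- lo + 1L
  hi <- min(add_years(birth_date, a_arr + 1L) - 1L, reference_date - 1L)
  while (hi >= lo && age_on(birth_date, hi) > a_arr) hi <- hi - 1L
  if (hi < lo) return(NULL)
  if (as.integer(hi - lo) >= 2L * margin_days + 1L) {
    lo <- lo + margin_days
    hi <- hi - margin_days
  }
  lo + sample.int(as.integer(hi - lo) + 1L, 1L) - 1L
}

sample_cohort_record <- function(group, country, cut_age_max, reference_date,
                                 margin_days) {
  spec <- cohort_age_ranges(cut_age_max)[[group]]
  m <- cut_age_max
  for (attempt in 1:50) {
    a_ref <- sample_int_range(spec$ref[1], spec$ref[2])
    birth <- sample_birth_date(reference_date, a_ref, margin_days)
    if (group %in% c("g2a", "g2b")) {
      return(list(
        birth_date = birth, generation = 2L,
        country_of_birth = NA_character_,
        mother_country = country, father_country = country,
        arrival_date = as.Date(NA)
      ))
    }
    arr_range <- switch(spec$arr,
      above = c(m + 1L, a_ref), # arrived older than the window
      below = c(0L, m), # arrived younger than / within the window
      within = c(0L, a_ref)
    )
    a_arr <- sample_int_range(arr_range[1], arr_range[2])
    arrival <- sample_arrival_date(birth, a_arr, reference_date, margin_days)
    if (is.null(arrival)) next
    return(list(
      birth_date = birth, generation = 1L,
      country_of_birth = country,
      mother_country = NA_character_, father_country = NA_character_,
      arrival_date = arrival
    ))
  }
  stop_fgmc(
    "could not construct a record for country ", country, ", group ",
    sub("^g", "", group)
  )
}

#' Generate a synthetic register hitting cohort marginals exactly
#'
#' Constructive (exact-marginal) mode of the synthetic-register generator.
#' Real population-register microdata of this kind cannot be shared, so this
#' generator emulates its structure: one row per female resident with birth
#' date, generation, origin countries and (for the first generation) arrival
#' date. Dates are sampled inside the age intervals that define each
#' requested cohort, so classifying the output with [tabulate_groups()] at
#' `reference_date` reproduces the requested per-country cohort counts
#' exactly. Output is deterministic given `seed`.
#'
#' @param counts Data frame with `country` and integer columns `g1a`, `g1b`,
#'   `g1c`, `g2a`, `g2b` (optionally `g1x`) giving the target marginals.
#' @param profiles An `fgmc_profiles` tibble; every country named in
#'   `counts` must be listed (the customary-age window is needed to place
#'   ages inside or outside it).
#' @param reference_date Analysis reference date; all generated arrival
#'   dates fall strictly before it.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param margin_days Safety margin (days) kept from the boundaries of each
#'   sampled date interval; set to 0 to exercise exact boundary dates (e.g.
#'   birthdays falling on the reference date itself).
#' @return A register tibble with columns `person_id`, `birth_date`,
#'   `generation`, `country_of_birth`, `mother_country`, `father_country`,
#'   `arrival_date`.
#' @examples
#' profiles <- load_profiles()
#' spec <- tibble::tibble(
#'   country = "Somalia", g1a = 10, g1b = 5, g1c = 3, g2a = 7, g2b = 2
#' )
#' reg <- generate_register(spec, profiles, seed = 42)
#' nrow(reg) # 27
#' @export
generate_register <- function(counts, profiles,
                              reference_date = as.Date("2013-01-01"),
                              seed = 1L, margin_days = 1L) {
  reference_date <- as.Date(reference_date)
  counts <- group_counts(counts)
  if (anyNA(counts[count_cols])) {
    stop_fgmc("generator marginals contain missing cells")
  }

  # feasibility: group 1b needs an age strictly between the window and 18
  for (i in seq_len(nrow(counts))) {
    prof <- profile_for(profiles, counts$country[i])
    if (nrow(prof) == 0) {
      stop_fgmc("no profile for country: ", counts$country[i])
    }
    if (counts$g1b[i] > 0 && prof$cut_age_max + 1L > 17L) {
      stop_fgmc(
        "group 1b is infeasible for ", counts$country[i],
        ": customary age window reaches ", prof$cut_age_max,
        ", leaving no age both past the window and under 18"
      )
    }
  }

  reg <- with_preserved_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(counts))) {
      prof <- profile_for(profiles, counts$country[i])
      for (grp in count_cols) {
        n <- counts[[grp]][i]
        if (n == 0) next
        for (k in seq_len(n)) {
          rows[[length(rows) + 1L]] <- sample_cohort_record(
            grp, prof$country, prof$cut_age_max, reference_date, margin_days
          )
        }
      }
    }
    if (length(rows) == 0) {
      empty_register()
    } else {
      out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
      dplyr::mutate(out,
        person_id = sprintf("P%06d", dplyr::row_number()),
        .before = 1
      )
    }
  })
  if (nrow(reg) == 0) {
    return(reg)
  }

  # internal consistency check: the classifier must see the marginals back
  got <- tabulate_groups(reg, profiles, reference_date)
  want <- dplyr::filter(counts, .data$total > 0)
  idx <- match(norm_country(want$country), norm_country(got$country))
  same <- !anyNA(idx) && nrow(got) == nrow(want) &&
    identical(
      unname(as.matrix(got[idx, count_cols])),
      unname(matrix(as.integer(as.matrix(want[, count_cols])), nrow = nrow(want)))
    )
  if (!same) {
    stop_fgmc("internal error: generated register does not reproduce marginals")
  }
  reg
}

empty_register <- function() {
  tibble::tibble(
    person_id = character(), birth_date = as.Date(character()),
    generation = integer(), country_of_birth = character(),
    mother_country = character(), father_country = character(),
    arrival_date = as.Date(character())
  )
}

#' Simulate a synthetic register from demographic rates
#'
#' Stochastic (rates) mode of the generator: per country, cohort counts are
#' drawn from a multinomial over the six cohorts and the records are then
#' constructed as in [generate_register()]. Useful for property tests and
#' for exercising the pipeline on populations that do not match any
#' published table.
#'
#' @param rates Data frame with `country`, `size` (total residents) and
#'   cohort probability columns `p_1a`, `p_1b`, `p_1c`, `p_1x`, `p_2a`,
#'   `p_2b` (need not sum to one; they are normalised).
#' @inheritParams generate_register
#' @return A register tibble.
#' @export
simulate_register <- function(rates, profiles,
                              reference_date = as.Date("2013-01-01"),
                              seed = 1L, margin_days = 1L) {
  p_cols <- paste0("p_", sub("^g", "", count_cols))
  need <- setdiff(c("country", "size", p_cols), names(rates))
  if (length(need) > 0) {
    stop_fgmc("rates lack column(s): ", paste(need, collapse = ", "))
  }
  counts <- with_preserved_seed(seed, {
    drawn <- lapply(seq_len(nrow(rates)), function(i) {
      p <- as.numeric(rates[i, p_cols])
      if (any(p < 0) || sum(p) <= 0) stop_fgmc("invalid cohort probabilities")
      n <- stats::rmultinom(1, size = rates$size[i], prob = p / sum(p))[, 1]
      tibble::tibble(
        country = rates$country[i],
        g1a = n[1], g1b = n[2], g1c = n[3], g1x = n[4], g2a = n[5], g2b = n[6]
      )
    })
    dplyr::bind_rows(drawn)
  })
  generate_register(counts, profiles, reference_date,
    seed = seed + 1L, margin_days = margin_days
  )
}

#' Read / write register microdata
#'
#' The register file is delimiter-separated with columns `person_id`,
#' `birth_date`, `generation`, `country_of_birth`, `mother_country`,
#' `father_country`, `arrival_date`; dates are ISO-8601 (`YYYY-MM-DD`) and
#' inapplicable fields (e.g. `arrival_date` for the second generation) are
#' empty. Reading validates every row and reports the first offending line:
#' malformed dates, a generation outside \{1, 2\}, a first-generation row
#' without an arrival date or with arrival before birth, or a
#' second-generation row with an arrival date.
#'
#' @param records Register tibble.
#' @param path File path.
#' @param delim Field delimiter, default `","`.
#' @return `read_register()` returns the validated register tibble;
#'   `write_register()` returns `path` invisibly.
#' @export
read_register <- function(path, delim = ",") {
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE
  )
  need <- setdiff(register_cols, names(raw))
  if (length(need) > 0) {
    stop_fgmc("register file lacks column(s): ", paste(need, collapse = ", "))
  }
  line <- seq_len(nrow(raw)) + 1L # header is line 1

  parse_date <- function(x, what, required) {
    blank <- !nzchar(trimws(x))
    d <- as.Date(rep(NA_character_, length(x)))
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", trimws(x))
    d[ok] <- suppressWarnings(as.Date(trimws(x)[ok]))
    bad <- (!blank & (is.na(d) & !blank & !ok)) | (ok & is.na(d)) |
      (required & blank)
    if (any(bad)) {
      stop_fgmc(
        "register line ", line[which(bad)[1]], ": malformed or missing ",
        what, " '", x[which(bad)[1]], "'"
      )
    }
    d
  }

  gen <- suppressWarnings(as.integer(trimws(raw$generation)))
  bad_gen <- is.na(gen) | !gen %in% c(1L, 2L)
  if (any(bad_gen)) {
    stop_fgmc(
      "register line ", line[which(bad_gen)[1]],
      ": generation must be 1 or 2, got '", raw$generation[which(bad_gen)[1]], "'"
    )
  }
  birth <- parse_date(raw$birth_date, "birth_date", required = TRUE)
  arrival <- parse_date(raw$arrival_date, "arrival_date", required = FALSE)

  miss_arr <- gen == 1L & is.na(arrival)
  if (any(miss_arr)) {
    stop_fgmc(
      "register line ", line[which(miss_arr)[1]],
      ": first-generation record without arrival_date"
    )
  }
  has_arr2 <- gen == 2L & !is.na(arrival)
  if (any(has_arr2)) {
    stop_fgmc(
      "register line ", line[which(has_arr2)[1]],
      ": second-generation record must not carry an arrival_date"
    )
  }
  early <- !is.na(arrival) & arrival < birth
  if (any(early)) {
    stop_fgmc(
      "register line ", line[which(early)[1]], ": arrival_date before birth_date"
    )
  }

  blank_to_na <- function(x) ifelse(nzchar(trimws(x)), trimws(x), NA_character_)
  tibble::tibble(
    person_id = trimws(raw$person_id),
    birth_date = birth,
    generation = gen,
    country_of_birth = blank_to_na(raw$country_of_birth),
    mother_country = blank_to_na(raw$mother_country),
    father_country = blank_to_na(raw$father_country),
    arrival_date = arrival
  )
}

#' @rdname read_register
#' @export
write_register <- function(records, path, delim = ",") {
  out <- records[, register_cols]
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  out$arrival_date <- ifelse(is.na(records$arrival_date), "",
    format(records$arrival_date, "%Y-%m-%d"))
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
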