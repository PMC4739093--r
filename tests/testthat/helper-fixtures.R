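# shared fixtures, loaded once per test run

ref_profiles <- load_profiles()

completed_counts_path <- system.file(
  "extdata", "group_counts_completed_synthetic.csv",
  package = "fgmcprev", mustWork = TRUE
)
printed_counts_path <- system.file(
  "extdata", "group_counts_printed.csv",
  package = "fgmcprev", mustWork = TRUE
)

completed_counts <- read_group_counts(completed_counts_path)
printed_counts <- read_group_counts(printed_counts_path)

reference_date <- as.Date("2013-01-01")

add_years_test <- function(d, n) lubridate::`%m+%`(d, lubridate::years(n))

# a tiny register builder for hand-traced classification cases
make_record <- function(birth, generation, country = NA, mother = NA,
                        father = NA, arrival = NA) {
  tibble::tibble(
    person_id = "P1",
    birth_date = as.Date(birth),
    generation = as.integer(generation),
    country_of_birth = as.character(country),
    mother_country = as.character(mother),
    father_country = as.character(father),
    arrival_date = as.Date(arrival)
  )
}

# minimal synthetic profile table for controlled-parameter tests
toy_profiles <- function(prev49 = 0.5, prev19 = 0.5, amin = 0L, amax = 9L,
                         t3_49 = 0.5, t3_19 = 0.5, country = "Testland") {
  tibble::tibble(
    country = country,
    prev_15_49 = prev49, prev_15_19 = prev19,
    cut_age_min = amin, cut_age_max = amax,
    type3_15_49 = t3_49, type3_15_19 = t3_19,
    type3_assumed_zero = FALSE,
    source = "synthetic"
  )
}

# random feasible marginal spec over countries whose window permits cohort 1b
random_feasible_spec <- function(n_countries = 3, max_count = 6) {
  feasible <- ref_profiles$country[ref_profiles$cut_age_max <= 16]
  ctry <- sample(feasible, n_countries)
  tibble::tibble(
    country = ctry,
    g1a = sample(0:max_count, n_countries, replace = TRUE),
    g1b = sample(0:max_count, n_countries, replace = TRUE),
    g1c = sample(0:max_count, n_countries, replace = TRUE),
    g1x = sample(0:max_count, n_countries, replace = TRUE),
    g2a = sample(0:max_count, n_countries, replace = TRUE),
    g2b = sample(0:max_count, n_countries, replace = TRUE)
  )
}
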