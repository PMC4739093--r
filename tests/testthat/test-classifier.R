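test_that("age_on counts completed birthday-based years", {
  expect_equal(age_on(as.Date("2004-05-01"), as.Date("2013-01-01")), 8L)
  # the anniversary itself counts as attained
  expect_equal(age_on(as.Date("2004-05-01"), as.Date("2012-05-01")), 8L)
  expect_equal(age_on(as.Date("2004-05-01"), as.Date("2012-04-30")), 7L)
  # exact 18th-birthday boundary used by the under-18 rules
  expect_equal(age_on(as.Date("1995-01-01"), as.Date("2013-01-01")), 18L)
  # leap-day births attain their birthday on 1 March of non-leap years
  expect_equal(age_on(as.Date("2000-02-29"), as.Date("2013-02-28")), 12L)
  expect_equal(age_on(as.Date("2000-02-29"), as.Date("2013-03-01")), 13L)
  expect_error(
    age_on(as.Date("2013-01-02"), as.Date("2013-01-01")),
    "precedes"
  )
})

test_that("records are attributed to origin countries by the mother's-country rule", {
  recs <- dplyr::bind_rows(
    make_record("2000-01-15", 2, mother = "Somalia", father = "Eritrea"),
    make_record("2000-01-15", 2, mother = "Somalia", father = "Norway"),
    make_record("2000-01-15", 2, mother = "Norway", father = "Somalia"),
    make_record("2000-01-15", 2, mother = "Norway", father = "Sweden"),
    make_record("1990-01-15", 1, country = "Somalia", arrival = "2005-06-01"),
    make_record("1990-01-15", 1, country = "Norway", arrival = "2005-06-01"),
    make_record("1990-01-15", 1, country = "eritrea ", arrival = "2005-06-01")
  )
  out <- attributed_country(recs, ref_profiles)
  expect_equal(
    out$attributed_country,
    c("Somalia", NA, NA, NA, "Somalia", NA, "Eritrea")
  )
})

test_that("cohort assignment follows the customary-age window rules", {
  # Somali window is 5-9; reference date 2013-01-01
  cases <- list(
    # arrived at 12 (> 9): assumed already subjected -> 1a
    list(birth = "1995-03-10", arrival = "2007-06-01", group = "1a"),
    # arrived at 6, now 14: past the window, under 18 -> 1b
    list(birth = "1998-03-10", arrival = "2004-06-01", group = "1b"),
    # arrived at 6, now 8: still within the window -> 1c
    list(birth = "2004-03-10", arrival = "2010-06-01", group = "1c"),
    # arrived at 6, now 20: residual bucket -> 1x
    list(birth = "1992-03-10", arrival = "1998-06-01", group = "1x"),
    # arrival on the upper margin (age 9) counts as within -> not 1a
    list(birth = "2003-03-10", arrival = "2012-06-01", group = "1c")
  )
  for (cs in cases) {
    rec <- make_record(cs$birth, 1, country = "Somalia", arrival = cs$arrival)
    got <- classify_records(rec, ref_profiles, reference_date)$group
    expect_equal(as.character(got), cs$group, info = cs$birth)
  }

  # second generation is split only on the 18th birthday
  gen2 <- dplyr::bind_rows(
    make_record("1995-06-01", 2, mother = "Somalia", father = "Somalia"), # 17
    make_record("1995-01-01", 2, mother = "Somalia", father = "Somalia"), # 18 today
    make_record("1990-01-01", 2, mother = "Somalia", father = "Somalia")
  )
  expect_equal(
    as.character(classify_records(gen2, ref_profiles, reference_date)$group),
    c("2a", "2b", "2b")
  )

  expect_error(
    classify_records(
      make_record("1990-01-01", 1, country = "Somalia"),
      ref_profiles, reference_date
    ),
    "arrival_date"
  )
})

test_that("calendar-year age mode shifts assignments as register statistics do", {
  rec <- make_record("1995-06-01", 2, mother = "Somalia", father = "Somalia")
  # birthday-based: 17 -> 2a; calendar-year: 2013 - 1995 = 18 -> 2b
  expect_equal(
    as.character(classify_records(rec, ref_profiles, reference_date)$group),
    "2a"
  )
  expect_equal(
    as.character(classify_records(rec, ref_profiles, reference_date,
      age_mode = "calendar_year"
    )$group),
    "2b"
  )
})

test_that("tabulation partitions every record into one cell plus the excluded bucket", {
  spec <- tibble::tibble(
    country = c("Somalia", "Eritrea"),
    g1a = c(10L, 4L), g1b = c(5L, 2L), g1c = c(3L, 1L),
    g2a = c(7L, 5L), g2b = c(2L, 0L)
  )
  reg <- generate_register(spec, ref_profiles, reference_date, seed = 11)
  excluded <- dplyr::bind_rows(
    make_record("1990-01-01", 1, country = "Norway", arrival = "2005-01-01"),
    make_record("2000-01-01", 2, mother = "Somalia", father = "Norway")
  )
  all_recs <- dplyr::bind_rows(reg, excluded)
  tab <- tabulate_groups(all_recs, ref_profiles, reference_date)

  expect_equal(attr(tab, "excluded"), 2L)
  expect_equal(sum(tab$total) + attr(tab, "excluded"), nrow(all_recs))
  expect_equal(tab$total, rowSums(tab[, c("g1a", "g1b", "g1c", "g1x", "g2a", "g2b")]))
  som <- tab[tab$country == "Somalia", ]
  expect_equal(
    unlist(som[, c("g1a", "g1b", "g1c", "g2a", "g2b")], use.names = FALSE),
    c(10L, 5L, 3L, 7L, 2L)
  )

  # empty input gives an empty (all-zero) table
  empty_tab <- tabulate_groups(reg[0, ], ref_profiles, reference_date)
  expect_equal(nrow(empty_tab), 0)
  expect_equal(attr(empty_tab, "excluded"), 0L)

  # folding the residual bucket moves 1x into 1a without changing totals
  spec1x <- tibble::tibble(
    country = "Somalia", g1a = 2L, g1b = 0L, g1c = 0L, g1x = 3L,
    g2a = 0L, g2b = 0L
  )
  reg1x <- generate_register(spec1x, ref_profiles, reference_date, seed = 5)
  folded <- tabulate_groups(reg1x, ref_profiles, reference_date, fold_g1x = TRUE)
  expect_equal(folded$g1a, 5L)
  expect_equal(folded$g1x, 0L)
  expect_equal(folded$total, 5L)
})

test_that("moving the reference date later never reverses protective transitions", {
  set.seed(202)
  spec <- random_feasible_spec(n_countries = 4, max_count = 8)
  reg <- generate_register(spec, ref_profiles, reference_date, seed = 21)
  now <- classify_records(reg, ref_profiles, reference_date)$group
  for (shift in c(1, 5, 12)) {
    later_date <- add_years_test(reference_date, shift)
    later <- classify_records(reg, ref_profiles, later_date)$group
    expect_true(all(later[now == "1a"] == "1a"))
    from_closed <- now %in% c("2b", "1x")
    expect_false(any(later[from_closed] %in% c("1b", "1c", "2a")))
  }
})

test_that("widening the customary window never increases the 1a cohort", {
  set.seed(203)
  spec <- random_feasible_spec(n_countries = 4, max_count = 8)
  reg <- generate_register(spec, ref_profiles, reference_date, seed = 22)
  base <- tabulate_groups(reg, ref_profiles, reference_date)
  for (extra in 1:3) {
    wider <- ref_profiles
    wider$cut_age_max <- pmin(wider$cut_age_max + extra, 18L)
    tab <- tabulate_groups(reg, wider, reference_date)
    joined <- dplyr::left_join(
      base[, c("country", "g1a")], tab[, c("country", "g1a")],
      by = "country", suffix = c("_base", "_wide")
    )
    expect_true(all(joined$g1a_wide <= joined$g1a_base))
  }
})
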