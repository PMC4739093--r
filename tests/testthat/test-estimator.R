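somalia_counts <- group_counts(tibble::tibble(
  country = "Somalia", g1a = 8873L, g1b = 1630L, g1c = 593L,
  g2a = 3654L, g2b = 206L
))

test_that("undergone estimates extrapolate the 15-49 prevalence onto cohort 1a", {
  counts <- group_counts(tibble::tibble(
    country = c("Somalia", "Eritrea", "Iraq"),
    g1a = c(8873L, 4508L, 7285L), g1b = 0L, g1c = 0L, g2a = 0L, g2b = 0L
  ))
  u <- estimate_undergone(counts, ref_profiles)
  expect_equal(u$undergone_unrounded,
    c(8873 * 0.979, 4508 * 0.887, 7285 * 0.081),
    tolerance = 1e-12
  )
  expect_equal(u$undergone, c(8687, 3999, 590))

  # zero prevalence nullifies the estimate
  zero <- estimate_undergone(
    group_counts(tibble::tibble(country = "Testland", g1a = 100L, g1b = 0L,
      g1c = 0L, g2a = 0L, g2b = 0L)),
    toy_profiles(prev49 = 0)
  )
  expect_equal(zero$undergone, 0)

  expect_error(
    estimate_undergone(
      group_counts(tibble::tibble(country = "Atlantis", g1a = 5L, g1b = 0L,
        g1c = 0L, g2a = 0L, g2b = 0L)),
      ref_profiles
    ),
    "no profile"
  )
  # g1a is complete in the printed table, so the undergone estimate runs
  # once the pooled residual row (which has no single profile) is set aside
  named_only <- dplyr::filter(printed_counts, country != "Other countries")
  expect_silent(estimate_undergone(group_counts(named_only), ref_profiles))
})

test_that("undergone type split uses the complement convention by default", {
  counts <- group_counts(tibble::tibble(
    country = c("Eritrea", "Somalia", "Iraq"),
    g1a = c(4508L, 8873L, 7285L), g1b = 0L, g1c = 0L, g2a = 0L, g2b = 0L
  ))
  s <- split_undergone_types(estimate_undergone(counts, ref_profiles), ref_profiles)
  expect_equal(s$undergone_type3, c(1543, 6889, 0))
  expect_equal(s$undergone_other, c(2456, 1798, 590))
  # complement: the pair sums to the rounded total exactly
  expect_equal(s$undergone_type3 + s$undergone_other, s$undergone)
  # assumed-zero typology is flagged through
  expect_equal(s$type3_assumed_zero, c(FALSE, FALSE, TRUE))

  # independent convention rounds both cells from the unrounded base
  cfg_ind <- scenario_config(type_split_undergone = "independent")
  s2 <- split_undergone_types(
    estimate_undergone(counts, ref_profiles, cfg_ind), ref_profiles, cfg_ind
  )
  expect_equal(s2$undergone_other[1], round(4508 * 0.887 * 0.614))
})

test_that("potentially at risk combines cohorts 1b, 1c, 2a without prevalence", {
  eritrea <- group_counts(tibble::tibble(
    country = "Eritrea", g1a = 4508L, g1b = 218L, g1c = 10L,
    g2a = 606L, g2b = 107L
  ))
  expect_equal(potentially_at_risk(eritrea)$potentially_at_risk, 834)
  expect_equal(
    potentially_at_risk(group_counts(tibble::tibble(
      country = "Eritrea", g1a = 0L, g1b = 0L, g1c = 0L, g2a = 0L, g2b = 0L
    )))$potentially_at_risk,
    0
  )
  expect_error(
    potentially_at_risk(printed_counts),
    "suppressed"
  )
})

test_that("risk scenarios weight the second generation by the acculturation factor", {
  r <- estimate_risk(somalia_counts, ref_profiles)
  expect_equal(r$risk_low_unrounded, (1630 + 593) * 0.967, tolerance = 1e-12)
  expect_equal(r$risk_low, 2150)
  expect_equal(r$risk_high_unrounded, (1630 + 593 + 3654) * 0.967, tolerance = 1e-12)
  expect_equal(r$risk_high, 5683)

  iraq <- group_counts(tibble::tibble(
    country = "Iraq", g1a = 7285L, g1b = 1949L, g1c = 416L,
    g2a = 3422L, g2b = 146L
  ))
  expect_equal(estimate_risk(iraq, ref_profiles)$risk_high, 284)

  # no second generation: the factor cancels and low == high
  no2a <- group_counts(tibble::tibble(
    country = "Somalia", g1a = 0L, g1b = 10L, g1c = 5L, g2a = 0L, g2b = 0L
  ))
  r0 <- estimate_risk(no2a, ref_profiles)
  expect_equal(r0$risk_low, r0$risk_high)

  # a continuous factor interpolates between the scenarios
  half <- estimate_risk(somalia_counts, ref_profiles,
    scenario_config(acculturation_factor_gen2 = 0.5)
  )
  expect_equal(half$risk_unrounded, (1630 + 593 + 0.5 * 3654) * 0.967,
    tolerance = 1e-12
  )
  expect_true(half$risk > r$risk_low && half$risk < r$risk_high)
  expect_error(
    scenario_config(acculturation_factor_gen2 = 1.2),
    "\\[0, 1\\]"
  )
})

test_that("risk type split rounds independently from the unrounded base", {
  eritrea <- group_counts(tibble::tibble(
    country = "Eritrea", g1a = 0L, g1b = 218L, g1c = 10L, g2a = 606L, g2b = 0L
  ))
  r <- split_risk_types(estimate_risk(eritrea, ref_profiles), ref_profiles)
  expect_equal(r$risk_low_type3, 60) # 178.752 * 0.338
  expect_equal(r$risk_low_other, 118) # 178.752 * 0.662
  # independent rounding: pair may undershoot the rounded total by one
  expect_equal(r$risk_low_type3 + r$risk_low_other, r$risk_low - 1)
  expect_equal(r$risk_high_type3, 221)
  expect_equal(r$risk_high_other, 433)

  som <- split_risk_types(estimate_risk(somalia_counts, ref_profiles), ref_profiles)
  expect_equal(som$risk_high_type3, 4319)
  expect_equal(som$risk_high_other, 1364)

  # zero share sends everything to the other-types cell
  zero_share <- split_risk_types(
    estimate_risk(
      group_counts(tibble::tibble(country = "Testland", g1a = 0L, g1b = 10L,
        g1c = 0L, g2a = 10L, g2b = 0L)),
      toy_profiles(t3_19 = 0)
    ),
    toy_profiles(t3_19 = 0)
  )
  expect_equal(zero_share$risk_low_type3, 0)
  expect_equal(zero_share$risk_low_other, zero_share$risk_low)

  # complement convention forces the pair to sum to the rounded total
  cfg_c <- scenario_config(type_split_risk = "complement")
  rc <- split_risk_types(estimate_risk(eritrea, ref_profiles, cfg_c),
    ref_profiles, cfg_c
  )
  expect_equal(rc$risk_low_type3 + rc$risk_low_other, rc$risk_low)
})

test_that("rounding mode is configurable and half-away is the default", {
  counts <- group_counts(tibble::tibble(
    country = "Testland", g1a = 5L, g1b = 0L, g1c = 0L, g2a = 0L, g2b = 0L
  ))
  tp <- toy_profiles(prev49 = 0.5) # 5 * 0.5 = 2.5: an exact tie
  away <- estimate_undergone(counts, tp)
  even <- estimate_undergone(counts, tp, scenario_config(rounding = "half-even"))
  expect_equal(away$undergone, 3)
  expect_equal(even$undergone, 2)
})

test_that("estimator invariants hold on the full country table", {
  est <- fgmc_estimate(completed_counts, ref_profiles)
  ct <- est$countries

  expect_true(all(ct$risk_low <= ct$risk_high))
  expect_true(all(ct$undergone <= ct$g1a))
  expect_true(all(ct$risk_high <= ct$potentially_at_risk))
  expect_true(all(ct$undergone >= 0 & ct$risk_low >= 0))
  expect_equal(ct$potentially_at_risk, ct$g1b + ct$g1c + ct$g2a)
  expect_equal(ct$undergone_type3 + ct$undergone_other, ct$undergone)

  # saturated prevalence turns the extrapolation into plain counts
  sat <- dplyr::mutate(ref_profiles, prev_15_49 = 1, prev_15_19 = 1)
  est1 <- fgmc_estimate(completed_counts, sat)
  expect_equal(est1$countries$undergone, est1$countries$g1a)
  expect_equal(est1$countries$risk_high, est1$countries$potentially_at_risk)

  # estimates are monotone in prevalence
  damp <- dplyr::mutate(ref_profiles,
    prev_15_49 = prev_15_49 * 0.5, prev_15_19 = prev_15_19 * 0.5
  )
  est_d <- fgmc_estimate(completed_counts, damp)
  expect_true(all(est_d$countries$undergone <= ct$undergone))
  expect_true(all(est_d$countries$risk_high <= ct$risk_high))
})

test_that("national summary, broom methods and plots are coherent", {
  est <- fgmc_estimate(completed_counts, ref_profiles)
  s <- national_summary(est)
  ct <- est$countries

  expect_equal(s$population, sum(ct$total))
  expect_equal(s$undergone_total, sum(ct$undergone))
  expect_equal(s$undergone_share, s$undergone_total / s$population)
  expect_equal(
    s$type3_share_of_undergone,
    s$undergone_type3_total / s$undergone_total
  )
  expect_equal(s$potentially_at_risk_total, sum(ct$g1b + ct$g1c + ct$g2a))
  expect_true(s$risk_low_total <= s$risk_high_total)

  expect_equal(broom::glance(est), s)
  long <- broom::tidy(est)
  expect_true(all(c("country", "quantity", "value") %in% names(long)))
  expect_equal(nrow(long), nrow(ct) * (ncol(ct) - 1))

  expect_s3_class(ggplot2::autoplot(est), "ggplot")
  expect_s3_class(ggplot2::autoplot(est, type = "types"), "ggplot")
  expect_s3_class(plot_risk_interval(est), "ggplot")
  expect_output(print(est), "potentially at risk")

  # a zero-population edge case reports zero shares rather than NaN
  none <- fgmc_estimate(
    group_counts(tibble::tibble(country = "Somalia", g1a = 0L, g1b = 0L,
      g1c = 0L, g2a = 0L, g2b = 0L)),
    ref_profiles
  )
  expect_equal(none$summary$undergone_share, 0)
  expect_equal(none$summary$type3_share_of_undergone, 0)
})
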