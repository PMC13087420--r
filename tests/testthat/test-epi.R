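test_that("carrier_frequency reports fractions and truncated reciprocals", {
  cf <- carrier_frequency(13 + 47, 589724)
  expect_equal(cf$fraction, 60 / 589724)
  expect_equal(cf$reciprocal_display, 9828)

  cf2 <- carrier_frequency(111, 589724)
  expect_equal(cf2$fraction, 111 / 589724)
  expect_equal(cf2$reciprocal_display, 5312)

  expect_equal(carrier_frequency(10, 10)$fraction, 1)
  z <- carrier_frequency(0, 100)
  expect_equal(z$fraction, 0)
  expect_identical(z$reciprocal_display, Inf)
})

test_that("compound_het_frequency applies the quarter-factor product", {
  ch <- compound_het_frequency(1 / 35, 1 / 9828)
  expect_equal(ch$reciprocal, 35 * 9828 * 4)
  expect_equal(ch$reciprocal_millions_display, 1.37)

  ch2 <- compound_het_frequency(1 / 35, 111 / 589724)
  expect_equal(ch2$reciprocal_display, 743796)

  expect_equal(compound_het_frequency(1, 1)$fraction, 1 / 4)
  # the optional unordered-parents factor doubles the frequency
  expect_equal(compound_het_frequency(1 / 35, 1 / 9828,
                                      count_parent_orders = TRUE)$fraction,
               2 * compound_het_frequency(1 / 35, 1 / 9828)$fraction)
})

test_that("expected counts floor and the births display rule holds", {
  expect_equal(expected_individuals(1.13e9, 1 / 1.37e6), 824L)
  expect_equal(expected_individuals(1.13e9, 1 / 743796), 1519L)
  expect_equal(expected_individuals(5e6, 0), 0L)

  b <- expected_annual_births(3.67e6, 1 / 1.37e6)
  expect_equal(b$display, 2.6)
  b2 <- expected_annual_births(3.67e6, 1 / 743796)
  expect_equal(b2$display, 5)
  expect_equal(expected_annual_births(1e6, 0.5, coverage = 0)$raw, 0)
})

test_that("the two-variant display-rounded chain reproduces end to end", {
  recs <- tibble::tibble(variant_id = c("855del4", "861del4"),
                         carrier_count = c(13L, 47L),
                         n_individuals = 589724L)
  est <- risk_report(recs, cohort_preset("eu"), rounding = "display")
  g <- glance(est)
  expect_equal(g$carrier_reciprocal_display, 9828)
  expect_equal(g$compound_het_reciprocal_millions, 1.37)
  expect_equal(g$expected_individuals, 824L)
  expect_equal(g$expected_births_display, 2.6)
  # per-variant rows present alongside the combined one
  expect_equal(nrow(tidy(est)), 3L)
})

test_that("the expanded-set exact chain reproduces end to end", {
  recs <- tibble::tibble(variant_id = "annealing_set",
                         carrier_count = 111L, n_individuals = 589724L)
  est <- risk_report(recs, cohort_preset("eu"), rounding = "exact")
  g <- glance(est)
  expect_equal(g$compound_het_reciprocal_display, 743796)
  expect_equal(g$expected_individuals, 1519L)
  expect_equal(g$expected_births_display, 5)
})

test_that("exact-path arithmetic carries full precision", {
  recs <- tibble::tibble(carrier_count = 60L, n_individuals = 589724L)
  est <- risk_report(recs, cohort_preset("eu"), rounding = "exact")
  expect_equal(est$combined$compound_het_reciprocal,
               35 * (589724 / 60) * 4, tolerance = 1e-12)
  # the display path is labelled as such in provenance
  expect_equal(est$provenance$rounding, "exact")
  est_d <- risk_report(recs, cohort_preset("eu"), rounding = "display")
  expect_equal(est_d$provenance$rounding, "display")
  expect_true(length(est$provenance$rounding_rules) >= 4)
})

test_that("risk chain is monotone in carrier counts and scale invariant", {
  cohort <- cohort_preset("eu")
  base <- risk_report(tibble::tibble(carrier_count = 50L,
                                     n_individuals = 589724L), cohort,
                      rounding = "exact")$combined
  withr::local_seed(13L)
  for (extra in sample(1:500, 20)) {
    more <- risk_report(tibble::tibble(carrier_count = 50L + extra,
                                       n_individuals = 589724L), cohort,
                        rounding = "exact")$combined
    expect_gte(more$expected_individuals, base$expected_individuals)
    expect_gte(more$expected_births_per_year, base$expected_births_per_year)
  }
  doubled <- risk_report(tibble::tibble(carrier_count = 100L,
                                        n_individuals = 2L * 589724L), cohort,
                         rounding = "exact")$combined
  half_base <- risk_report(tibble::tibble(carrier_count = 50L,
                                          n_individuals = 589724L), cohort,
                           rounding = "exact")$combined
  expect_equal(doubled$carrier_fraction, half_base$carrier_fraction)
  expect_equal(doubled$compound_het_fraction, half_base$compound_het_fraction)
})

test_that("mixed population strata are refused", {
  recs <- tibble::tibble(variant_id = c("a", "b"),
                         population = c("EUR", "EAS"),
                         carrier_count = c(5L, 6L),
                         n_individuals = 1000L)
  expect_error(risk_report(recs, cohort_preset("eu")), "strata")
})

test_that("screening coverage is applied only on request", {
  recs <- tibble::tibble(carrier_count = 60L, n_individuals = 589724L)
  full <- risk_report(recs, cohort_preset("eu"))$combined
  cov <- risk_report(recs, cohort_preset("eu"),
                     apply_coverage = TRUE)$combined
  expect_equal(cov$expected_births_per_year,
               0.64 * full$expected_births_per_year)
})

test_that("risk estimates plot", {
  recs <- tibble::tibble(carrier_count = 60L, n_individuals = 589724L)
  expect_s3_class(autoplot(risk_report(recs, cohort_preset("eu"))), "ggplot")
})
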