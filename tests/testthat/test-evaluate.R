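test_that("CAP diagnosis is primary-position membership in the code set", {
  expect_true(diagnose_cap(list(primary_icd = "J18.1")))
  expect_true(diagnose_cap(list(primary_icd = "J12.9")))
  expect_false(diagnose_cap(list(primary_icd = "I21.0")))
  # secondary-position CAP code does not qualify
  expect_false(diagnose_cap(list(icd_codes = c("I21.0", "J18.1"))))
  expect_true(diagnose_cap(list(icd_codes = c("J15.9", "I21.0"))))
  expect_error(diagnose_cap(list(icd_codes = character(0))),
               class = "wf_missing_field")
  # configurable code set
  expect_false(diagnose_cap(list(primary_icd = "J18.1"), cap_codes = "J12"))
})

test_that("max_severity takes the highest band over the journey", {
  expect_identical(max_severity(c("Low", "Low", "Moderate", "Low")),
                   "Moderate")
  expect_identical(max_severity("High"), "High")
  expect_identical(max_severity(rep("Low", 24)), "Low")
  expect_error(max_severity(character(0)), class = "wf_no_severity")
  expect_error(max_severity(c("Low", "Severe")), class = "wf_invalid_value")
})

test_that("review linkage honours the matching window and tie-breaks", {
  t0 <- as.POSIXct("2022-04-01 00:00:00", tz = "UTC")
  adm <- data.frame(admission_id = c("A1", "A2"),
                    patient_id = c("P1", "P2"),
                    admitted = c(t0, t0 + 48 * 3600),
                    discharged = c(t0 + 24 * 3600, t0 + 96 * 3600),
                    stringsAsFactors = FALSE)
  reviews <- data.frame(
    patient_id = c("P1", "P1", "P2"),
    admission_datetime = c(t0 + 2 * 3600,            # inside stay
                           t0 + 3 * 3600,            # second review, later
                           t0 + 96 * 3600 + 72 * 3600), # 3 days post-discharge
    band = c("Low", "High", "Moderate"), stringsAsFactors = FALSE)
  linked <- link_reviews(adm, reviews)
  expect_identical(nrow(linked$matched), 1L)
  # earliest review wins for the one matched admission
  expect_identical(linked$matched$band, "Low")
  expect_identical(linked$unmatched_admissions$admission_id, "A2")
  expect_identical(nrow(linked$unmatched_reviews), 2L)

  # a review inside the +/- tolerance just before admission matches
  reviews2 <- data.frame(patient_id = "P2",
                         admission_datetime = t0 + 48 * 3600 - 23 * 3600,
                         band = "High", stringsAsFactors = FALSE)
  expect_identical(nrow(link_reviews(adm, reviews2)$matched), 1L)
  expect_identical(nrow(link_reviews(adm, reviews2,
                                     tolerance_hours = 1)$matched), 0L)
})

test_that("the severity cross-tab tallies pairs with hand arithmetic", {
  pairs <- data.frame(reviewer_band = c("Low", "Moderate", "High"),
                      engine_band = c("Low", "High", "High"),
                      stringsAsFactors = FALSE)
  x <- crosstab_severity(pairs)
  expect_identical(sum(diag(x$counts)), 2L)
  expect_identical(x$agreement, 2L)
  expect_identical(x$counts["Moderate", "High"], 1L)
  expect_identical(x$engine_high_underscored, 1L)
  expect_identical(x$reviewer_over_engine, 0L)
  expect_equal(x$agreement_fraction, 2 / 3)
  # marginals sum to the pair count
  expect_identical(sum(x$counts), nrow(pairs))

  empty <- crosstab_severity(data.frame(reviewer_band = character(),
                                        engine_band = character()))
  expect_identical(sum(empty$counts), 0L)
  expect_true(is.na(empty$agreement_fraction))

  same <- crosstab_severity(data.frame(reviewer_band = rep("High", 5),
                                       engine_band = rep("High", 5)))
  expect_equal(same$agreement_fraction, 1.0)

  expect_error(crosstab_severity(data.frame(reviewer_band = "Severe",
                                            engine_band = "Low")),
               class = "wf_invalid_value")
})

test_that("reviewer-over-engine counts use the band ordering", {
  pairs <- data.frame(reviewer_band = c("High", "Moderate", "Low"),
                      engine_band = c("Low", "Low", "High"),
                      stringsAsFactors = FALSE)
  x <- crosstab_severity(pairs)
  expect_identical(x$reviewer_over_engine, 2L)
  expect_identical(x$engine_high_underscored, 1L)
})

test_that("an error-free fully-reviewed cohort evaluates to exact agreement", {
  cfg <- sim_config(n_admissions = 50, seed = 17, reviewer_error = 0,
                    review_fraction = 1, review_score_missing = 0)
  sim <- simulate_cohort(cfg)
  reviews <- simulate_reviews(sim$truth, cfg)
  ev <- evaluate_severity(as_store(sim$messages), reviews)
  expect_identical(ev$n_cap, sum(sim$truth$is_cap))
  expect_identical(ev$n_reviewed, ev$n_cap)
  expect_equal(ev$pct_agree, 100)
  # error-free reviewer: the cross-tab is exactly diagonal
  off_diag <- ev$crosstab$counts
  diag(off_diag) <- 0L
  expect_true(all(off_diag == 0L))
  # arithmetic consistency
  expect_identical(ev$n_reviewed + ev$n_not_reviewed, ev$n_cap)
  expect_identical(sum(ev$crosstab$counts), ev$n_compared)
})

test_that("a cohort with no CAP admissions evaluates without failure", {
  cfg <- sim_config(n_admissions = 20, seed = 19, cap_fraction = 0)
  sim <- simulate_cohort(cfg)
  reviews <- simulate_reviews(sim$truth, cfg)
  ev <- evaluate_severity(as_store(sim$messages), reviews)
  expect_identical(ev$n_cap, 0L)
  expect_identical(ev$n_reviewed, 0L)
  expect_identical(sum(ev$crosstab$counts), 0L)
})

test_that("review-score gaps surface as the with/without-score split", {
  cfg <- sim_config(n_admissions = 150, seed = 23, cap_fraction = 1,
                    review_fraction = 1, reviewer_error = 0,
                    review_score_missing = 0.3)
  sim <- simulate_cohort(cfg)
  reviews <- simulate_reviews(sim$truth, cfg)
  ev <- evaluate_severity(as_store(sim$messages), reviews)
  expect_identical(ev$n_reviewed, 150L)
  expect_lt(ev$n_with_reviewer_score, ev$n_reviewed)
  expect_identical(ev$n_compared, ev$n_with_reviewer_score)
})
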