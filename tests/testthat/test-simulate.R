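test_that("the simulated stream is fully seed-deterministic", {
  cfg <- sim_config(n_admissions = 40, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$messages$kind, b$messages$kind)
  expect_identical(a$messages$timestamp, b$messages$timestamp)
  expect_identical(a$messages$payload, b$messages$payload)
  # a different seed changes the stream
  c <- simulate_cohort(sim_config(n_admissions = 40, seed = 8))
  expect_false(identical(a$truth$admitted, c$truth$admitted))
})

test_that("cohort composition tracks the configured rates", {
  cfg <- sim_config(n_admissions = 1000, seed = 3, cap_fraction = 0.3)
  sim <- simulate_cohort(cfg)
  n_cap <- sum(sim$truth$is_cap)
  sd3 <- 3 * sqrt(1000 * 0.3 * 0.7)
  expect_lt(abs(n_cap - 300), sd3)
  # severity mix among CAP admissions
  mix <- table(factor(sim$truth$true_max_severity[sim$truth$is_cap],
                      levels = severity_bands())) / n_cap
  for (b in severity_bands()) {
    se3 <- 3 * sqrt(cfg$severity_mix[[b]] * (1 - cfg$severity_mix[[b]]) / n_cap)
    expect_lt(abs(mix[[b]] - cfg$severity_mix[[b]]), se3 + 1e-9)
  }
})

test_that("message timestamps lie within each admission interval", {
  cfg <- sim_config(n_admissions = 60, seed = 11)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  for (i in seq_len(nrow(sim$messages))) {
    id <- sim$messages$admission_id[i]
    row <- tr[tr$admission_id == id, ]
    expect_true(sim$messages$timestamp[i] >= row$admitted &&
                  sim$messages$timestamp[i] <= row$discharged)
  }
})

test_that("a pure-Low severity mix replays to Low for every CAP admission", {
  cfg <- sim_config(n_admissions = 40, seed = 13,
                    severity_mix = c(Low = 1, Moderate = 0, High = 0))
  sim <- simulate_cohort(cfg)
  run <- run_replay(cap_plan(), as_store(sim$messages))
  cap <- sim$truth[sim$truth$is_cap, ]
  for (id in cap$admission_id)
    expect_identical(max_severity(run$journeys[[id]]), "Low")
})

test_that("review volume matches the configured fraction", {
  cfg <- sim_config(n_admissions = 2000, seed = 5, cap_fraction = 1,
                    review_fraction = 0.45)
  sim <- simulate_cohort(cfg)
  reviews <- simulate_reviews(sim$truth, cfg)
  expect_lt(abs(nrow(reviews) - 900), 3 * sqrt(2000 * 0.45 * 0.55))
})

test_that("error-free reviewers reproduce the true band exactly", {
  cfg <- sim_config(n_admissions = 60, seed = 2, reviewer_error = 0,
                    review_score_missing = 0, review_fraction = 1)
  sim <- simulate_cohort(cfg)
  reviews <- simulate_reviews(sim$truth, cfg)
  cap <- sim$truth[sim$truth$is_cap, ]
  expect_identical(nrow(reviews), nrow(cap))
  expect_identical(reviews$band,
                   cap$true_max_severity[match(reviews$patient_id,
                                               cap$patient_id)])
})

test_that("forced reviewer error always changes the band, one level", {
  cfg <- sim_config(n_admissions = 80, seed = 4, reviewer_error = 1,
                    review_score_missing = 0, review_fraction = 1,
                    severity_mix = c(Low = 0, Moderate = 0, High = 1))
  sim <- simulate_cohort(cfg)
  reviews <- simulate_reviews(sim$truth, cfg)
  expect_true(all(reviews$band == "Moderate"))  # High perturbs down one level

  cfg2 <- sim_config(n_admissions = 80, seed = 4, reviewer_error = 1,
                     review_score_missing = 0, review_fraction = 1,
                     severity_mix = c(Low = 1, Moderate = 0, High = 0))
  sim2 <- simulate_cohort(cfg2)
  reviews2 <- simulate_reviews(sim2$truth, cfg2)
  expect_true(all(reviews2$band == "Moderate"))  # Low can only move up
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(severity_mix = c(Low = 0.5, Moderate = 0.5,
                                           High = 0.5)),
               class = "wf_config_error")
  expect_error(sim_config(n_admissions = 0), class = "wf_config_error")
  expect_error(sim_config(cap_fraction = 1.5), class = "wf_config_error")
})
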