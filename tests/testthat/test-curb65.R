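test_that("curb65_score matches the independent oracle on boundary grid", {
  grid <- expand.grid(confusion = c(TRUE, FALSE),
                      urea = c(6.9, 7.0, 7.1),
                      resp_rate = c(29, 30, 31),
                      systolic_bp = c(89, 90, 91),
                      diastolic_bp = c(59, 60, 61),
                      age = c(64L, 65L, 66L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- curb65_score(g$confusion, g$urea, g$resp_rate, g$systolic_bp,
                        g$diastolic_bp, g$age)$value
    want <- curb65_oracle(g$confusion, g$urea, g$resp_rate, g$systolic_bp,
                          g$diastolic_bp, g$age)
    expect_identical(got, want,
                     label = sprintf("row %d (%s)", i,
                                     paste(unlist(g), collapse = ",")))
  }
})

test_that("worked examples: none, all, and boundary-mixed factor sets", {
  expect_identical(curb65_score(FALSE, 5.0, 16, 120, 80, 40)$value, 0L)
  expect_identical(curb65_score(TRUE, 8.0, 32, 85, 60, 70)$value, 5L)
  # urea exactly 7 and systolic exactly 90 / diastolic 61 do not trigger;
  # respiratory rate 30 and age 65 do
  expect_identical(curb65_score(FALSE, 7.0, 30, 90, 61, 65)$value, 2L)
})

test_that("score is monotone in each factor and equals breakdown total", {
  combos <- expand.grid(conf = c(FALSE, TRUE), urea = c(FALSE, TRUE),
                        rr = c(FALSE, TRUE), bp = c(FALSE, TRUE),
                        age = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    on <- combos[i, ]
    inputs <- curb65_inputs_for(on$conf, on$urea, on$rr, on$bp, on$age)
    res <- do.call(curb65_score, inputs)
    expect_identical(res$value, sum(unlist(on)))
    expect_identical(res$value, sum(res$breakdown$points))
    expect_identical(res$breakdown$satisfied,
                     unname(unlist(on))[c(1, 2, 3, 4, 5)])
    # flipping any single unsatisfied factor on raises the score by 1
    for (f in names(combos)) {
      if (on[[f]]) next
      on2 <- on; on2[[f]] <- TRUE
      res2 <- do.call(curb65_score,
                      curb65_inputs_for(on2$conf, on2$urea, on2$rr, on2$bp,
                                        on2$age))
      expect_identical(res2$value, res$value + 1L)
    }
  }
})

test_that("severity banding is 0-1 Low, 2 Moderate, 3-5 High", {
  expect_identical(stratify_severity(0), "Low")
  expect_identical(stratify_severity(1), "Low")
  expect_identical(stratify_severity(2), "Moderate")
  expect_identical(stratify_severity(3), "High")
  expect_identical(stratify_severity(4), "High")
  expect_identical(stratify_severity(5), "High")
  expect_error(stratify_severity(6), class = "wf_invalid_value")
  expect_error(stratify_severity(-1), class = "wf_invalid_value")
  expect_error(stratify_severity(1.5), class = "wf_invalid_value")
})

test_that("banding partitions all factor combinations without gaps", {
  combos <- expand.grid(conf = c(FALSE, TRUE), urea = c(FALSE, TRUE),
                        rr = c(FALSE, TRUE), bp = c(FALSE, TRUE),
                        age = c(FALSE, TRUE))
  bands <- vapply(seq_len(nrow(combos)), function(i) {
    on <- combos[i, ]
    stratify_severity(do.call(
      curb65_score, curb65_inputs_for(on$conf, on$urea, on$rr, on$bp,
                                      on$age))$value)
  }, character(1))
  k <- rowSums(combos)
  expect_identical(bands, ifelse(k <= 1, "Low",
                                 ifelse(k == 2, "Moderate", "High")))
  expect_setequal(unique(bands), c("Low", "Moderate", "High"))
})

test_that("cut-offs are overridable for local guideline variants", {
  # raising the urea cut to 11 stops urea 9 from scoring
  base <- curb65_score(FALSE, 9, 18, 120, 80, 40)$value
  local <- curb65_score(FALSE, 9, 18, 120, 80, 40,
                        cutoffs = list(urea = 11))$value
  expect_identical(base, 1L)
  expect_identical(local, 0L)
})

test_that("missing inputs raise a missing-field condition", {
  algo <- curb65_algorithm()
  expect_error(run_algorithm(algo, list(confusion = TRUE, urea = 8)),
               class = "wf_missing_field")
})
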