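completed_run <- function() {
  run_replay(cap_plan(), worsening_store())
}

test_that("the journey diagram highlights exactly the visited steps", {
  run <- completed_run()
  jn <- run$journeys[["A1"]]
  pl <- cap_plan()
  mmd <- render_journey(jn, pl)
  expect_match(mmd, "^flowchart TD")
  # every plan step appears as a node
  for (nm in names(pl$steps))
    expect_match(mmd, paste0("\\b", nm, "\\b"))
  # the class line lists precisely the visited steps
  class_line <- grep("^    class ", strsplit(mmd, "\n")[[1]], value = TRUE)
  highlighted <- strsplit(sub("^    class ([^ ]+) visited;$", "\\1",
                              class_line), ",")[[1]]
  expect_setequal(highlighted, unique(jn$visits$step))
  expect_identical(length(highlighted), length(unique(jn$visits$step)))
})

test_that("direct_route_only drops unvisited branches", {
  run <- completed_run()
  jn <- run$journeys[["A1"]]
  pl <- cap_plan()
  mmd <- render_journey(jn, pl, direct_route_only = TRUE)
  expect_false(grepl("no_cap", mmd))          # never visited
  expect_false(grepl("moderate_severity", mmd))
  expect_true(grepl("low_severity", mmd))
  full <- render_journey(jn, pl)
  expect_true(grepl("no_cap", full))
})

test_that("show_sources annotates nodes with their input source", {
  run <- completed_run()
  mmd <- render_journey(run$journeys[["A1"]], cap_plan(), show_sources = TRUE)
  expect_match(mmd, "curb65_input")
})

test_that("a journey from another plan is rejected", {
  run <- completed_run()
  expect_error(render_journey(run$journeys[["A1"]], linear_plan()),
               class = "wf_inconsistent_journey")
})

test_that("factor breakdown rows flag satisfied factors and sum to the score", {
  res <- curb65_score(TRUE, 9, 20, 110, 70, 80)  # confusion + urea + age = 3
  html <- render_factor_breakdown(res)
  expect_identical(length(gregexpr("<tr class=\"satisfied\"", html)[[1]]), 3L)
  expect_identical(length(gregexpr("<tr class=\"unsatisfied\"", html)[[1]]), 2L)
  expect_match(html, "<td>Total</td><td></td><td>3</td>")

  res0 <- curb65_score(FALSE, 5, 16, 120, 80, 40)
  html0 <- render_factor_breakdown(res0)
  expect_identical(gregexpr("<tr class=\"satisfied\"", html0)[[1]][1], -1L)
})

test_that("results without a factor breakdown cannot be rendered as one", {
  sch <- data_schema("crp", list(data_field("crp", "number", required = TRUE)))
  lab <- run_algorithm(logical_algorithm("crp", sch, list(
    rule(condition_on("crp", ">=", 100), "high")), "normal"),
    list(crp = 150))
  expect_error(render_factor_breakdown(lab), class = "wf_no_breakdown")
})

test_that("prediction documents show both probabilities and ordered contributions", {
  algo <- x_only_predictive(constant_model(0.8))
  res <- run_algorithm(algo, list(x = 1))
  ex <- structure(data.frame(feature = c("a", "b"), value = c(1, 2),
                             contribution = c(0.1, -0.3)),
                  class = c("wf_explanation", "data.frame"))
  html <- render_prediction(res, ex)
  expect_match(html, "0\\.800")
  expect_match(html, "0\\.200")
  # ordered by |contribution|: b (-0.3) before a (+0.1)
  expect_lt(regexpr("<td>b</td>", html), regexpr("<td>a</td>", html))
  # rendering is pure: identical output bytes on re-render
  expect_identical(render_prediction(res, ex), html)
})

test_that("the model panel shows all five indicators to three decimals", {
  md <- model_metadata(0.876, 0.8, 0.9, 0.85, 0.889,
                       computed_on = "fixture")
  html <- render_model_panel(md)
  for (s in c("0\\.876", "0\\.800", "0\\.900", "0\\.850", "0\\.889"))
    expect_match(html, s)
  expect_match(html, "Predictive power")

  md_bad <- model_metadata(NA, 0.8, 0.9, 0.85, 0.9)
  expect_error(render_model_panel(md_bad), class = "wf_missing_metric")
})

test_that("the model panel renders from cached metadata without the model", {
  d <- separable_records()
  algo <- x_only_predictive(function(X) plogis(10 * X[, 1]))
  md <- compute_metadata(algo, d$records, d$labels)
  # metadata alone -- no model object in scope -- is enough to render
  html <- render_model_panel(md)
  expect_match(html, "1\\.000")
})
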