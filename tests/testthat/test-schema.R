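test_that("validate_record coerces, defaults, and enforces ranges", {
  sch <- bloods_schema()
  # numeric text is coerced
  expect_identical(validate_record(sch, list(urea = "8.1", crp = 12)),
                   list(urea = 8.1, crp = 12))
  # absent non-required field takes its default
  expect_identical(validate_record(sch, list(urea = 5))$crp, 0)
  # missing required field
  expect_error(validate_record(sch, list(crp = 3)),
               class = "wf_missing_field")

  rr <- data_schema("resp", list(
    data_field("rr", "integer", range = c(0, 80), required = TRUE)))
  expect_error(validate_record(rr, list(rr = 999)),
               class = "wf_invalid_value")
  expect_error(validate_record(rr, list(rr = 20.5)),
               class = "wf_invalid_value")
  expect_identical(validate_record(rr, list(rr = "24"))$rr, 24L)
})

test_that("boolean, category and datetime kinds validate", {
  sch <- data_schema("misc", list(
    data_field("confusion", "boolean", required = TRUE),
    data_field("ward", "category", choices = c("AMU", "ICU"), default = "AMU"),
    data_field("seen_at", "datetime")))
  rec <- validate_record(sch, list(confusion = "true",
                                   seen_at = "2022-04-01 10:00:00"))
  expect_true(rec$confusion)
  expect_identical(rec$ward, "AMU")
  expect_s3_class(rec$seen_at, "POSIXct")
  expect_error(validate_record(sch, list(confusion = TRUE, ward = "theatre")),
               class = "wf_invalid_value")
})

test_that("validate_record is idempotent", {
  sch <- data_schema("mix", list(
    data_field("urea", "number", required = TRUE),
    data_field("rr", "integer", default = 18L),
    data_field("confusion", "boolean", default = FALSE)))
  for (raw in list(list(urea = "9.9", rr = "31", confusion = "yes"),
                   list(urea = 3.2),
                   list(urea = 7, confusion = 1))) {
    once <- validate_record(sch, raw)
    expect_identical(validate_record(sch, once), once)
  }
})

test_that("a field cannot be both required and defaulted", {
  expect_error(data_field("x", "number", required = TRUE, default = 1),
               class = "wf_config_error")
  expect_error(data_field("x", "number", default = 200, range = c(0, 100)),
               class = "wf_invalid_value")
  expect_error(data_schema("s", list(data_field("a"), data_field("a"))),
               class = "wf_config_error")
})

test_that("collate merges disjoint sources and validates the union", {
  demo <- data_source("demo", data_schema("demo", list(
    data_field("age", "integer", required = TRUE))))
  lab <- data_source("lab", data_schema("lab", list(
    data_field("urea", "number", required = TRUE))))
  expect_identical(collate(list(demo, lab), list(list(age = 70),
                                                 list(urea = 8))),
                   list(age = 70L, urea = 8))
  expect_error(collate(list(demo, lab), list(list(), list())),
               class = "wf_missing_field")
})

test_that("field collisions resolve to the last source, by declared order", {
  a <- data_source("a", data_schema("a", list(data_field("urea", "number"))))
  b <- data_source("b", data_schema("b", list(data_field("urea", "number"))))
  expect_identical(collate(list(a, b), list(list(urea = 5), list(urea = 8))),
                   list(urea = 8))
  # swapping declaration order swaps the winner
  expect_identical(collate(list(b, a), list(list(urea = 8), list(urea = 5))),
                   list(urea = 5))
})

test_that("collate is associative over disjoint-field sources", {
  fields <- c("age", "urea", "rr")
  srcs <- lapply(fields, function(f)
    data_source(f, data_schema(f, list(data_field(f, "number")))))
  recs <- list(list(age = 70), list(urea = 8), list(rr = 22))
  flat <- collate(srcs, recs)
  # ((a + b) + c) via a nested collated source
  ab <- data_source("ab", data_schema("ab", list(
    data_field("age", "number"), data_field("urea", "number"))),
    constituents = srcs[1:2])
  nested <- data_source("abc", data_schema("abc", lapply(
    fields, data_field, kind = "number")), constituents = list(ab, srcs[[3]]))
  expect_identical(
    wardflow:::collate_source(nested, list(age = recs[[1]], urea = recs[[2]],
                                           rr = recs[[3]])),
    flat)
})

test_that("source transforms apply in declared order before validation", {
  double_x <- function(r) { r$x <- r$x * 2; r }
  add_one <- function(r) { r$x <- r$x + 1; r }
  src <- data_source("t", data_schema("t", list(data_field("x", "number"))),
                     transforms = list(double_x, add_one))
  expect_identical(collate(list(src), list(list(x = 3))), list(x = 7))
  src2 <- data_source("t", data_schema("t", list(data_field("x", "number"))),
                      transforms = list(add_one, double_x))
  expect_identical(collate(list(src2), list(list(x = 3))), list(x = 8))
})
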