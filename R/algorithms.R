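#' Risk factor conditions
#'
#' A risk factor is a named boolean predicate over schema fields carrying an
#' integer point weight. A factor holds one or more elementary conditions
#' (`field <op> value`, or a bare boolean field) combined with `"any"` or
#' `"all"`; CURB65's blood-pressure component, for instance, is
#' `any(systolic_bp < 90, diastolic_bp <= 60)`.
#'
#' @param field Schema field name the condition reads.
#' @param op One of `">"`, `">="`, `"<"`, `"<="`, `"=="`, `"!="`, `"in"`,
#'   `"is_true"`, `"is_false"`.
#' @param value Comparison value (unused for `is_true`/`is_false`; a vector
#'   for `"in"`).
#' @return `condition_on()` returns a `wf_condition`; `risk_factor()` a
#'   `wf_risk_factor`.
#' @export
condition_on <- function(field, op = "is_true", value = NULL) {
  ops <- c(">", ">=", "<", "<=", "==", "!=", "in", "is_true", "is_false")
  if (!op %in% ops)
    wf_abort("wf_config_error", sprintf("unknown condition operator '%s'", op))
  if (is.null(value) && !op %in% c("is_true", "is_false"))
    wf_abort("wf_config_error", sprintf("operator '%s' needs a value", op))
  structure(list(field = field, op = op, value = value), class = "wf_condition")
}

eval_condition <- function(cond, record) {
  v <- record[[cond$field]]
  if (is.null(v)) abort_missing_field(cond$field)
  switch(cond$op,
         ">" = v > cond$value, ">=" = v >= cond$value,
         "<" = v < cond$value, "<=" = v <= cond$value,
         "==" = v == cond$value, "!=" = v != cond$value,
         "in" = v %in% cond$value,
         "is_true" = isTRUE(v), "is_false" = isFALSE(v))
}

#' @param name Factor identifier.
#' @param conditions A single `wf_condition` or list of them.
#' @param combine `"any"` or `"all"` across conditions.
#' @param weight Non-negative integer points awarded when satisfied.
#' @rdname condition_on
#' @export
risk_factor <- function(name, conditions, combine = "any", weight = 1L) {
  if (inherits(conditions, "wf_condition")) conditions <- list(conditions)
  if (!all(vapply(conditions, inherits, logical(1), what = "wf_condition")))
    wf_abort("wf_config_error", "conditions must be built with condition_on()")
  if (!combine %in% c("any", "all"))
    wf_abort("wf_config_error", "combine must be 'any' or 'all'")
  weight <- as.integer(weight)
  if (is.na(weight) || weight < 0L)
    wf_abort("wf_config_error", "weight must be a non-negative integer")
  structure(list(name = name, conditions = conditions, combine = combine,
                 weight = weight),
            class = "wf_risk_factor")
}

factor_satisfied <- function(factor, record) {
  hits <- vapply(factor$conditions, eval_condition, logical(1), record = record)
  if (factor$combine == "any") any(hits) else all(hits)
}

#' Score algorithm: a weighted sum of risk factors
#'
#' The classic clinical risk-score modality: each satisfied factor
#' contributes its integer weight and the result value is the total. The
#' output range runs from 0 to the sum of weights.
#'
#' @param name Algorithm identifier.
#' @param schema Input [data_schema()].
#' @param factors List of [risk_factor()]s; every referenced field must be
#'   in the schema.
#' @return A `wf_score_algorithm`.
#' @export
score_algorithm <- function(name, schema, factors) {
  stopifnot(inherits(schema, "wf_schema"))
  if (inherits(factors, "wf_risk_factor")) factors <- list(factors)
  known <- schema_field_names(schema)
  for (f in factors) {
    used <- vapply(f$conditions, `[[`, character(1), "field")
    bad <- setdiff(used, known)
    if (length(bad))
      wf_abort("wf_config_error",
               sprintf("factor '%s' references unknown field(s): %s",
                       f$name, paste(bad, collapse = ", ")))
  }
  max_score <- sum(vapply(factors, `[[`, integer(1), "weight"))
  structure(list(name = name, schema = schema, factors = factors,
                 output_range = c(0L, as.integer(max_score))),
            class = c("wf_score_algorithm", "wf_algorithm"))
}

#' Logical algorithm: ordered if/then rules
#'
#' Rules are evaluated in declared order; the first rule whose condition
#' holds supplies the result label, otherwise `default_label`. Exactly one
#' label always results.
#'
#' @param name Algorithm identifier.
#' @param schema Input [data_schema()].
#' @param rules List of `list(condition = wf_condition, label = chr)` built
#'   with [rule()].
#' @param default_label Label when no rule matches.
#' @return A `wf_logical_algorithm`.
#' @export
logical_algorithm <- function(name, schema, rules, default_label) {
  stopifnot(inherits(schema, "wf_schema"))
  if (!all(vapply(rules, function(r)
    inherits(r$condition, "wf_condition") && is.character(r$label), logical(1))))
    wf_abort("wf_config_error", "rules must be built with rule()")
  structure(list(name = name, schema = schema, rules = rules,
                 default_label = default_label,
                 labels = unique(c(vapply(rules, `[[`, character(1), "label"),
                                   default_label))),
            class = c("wf_logical_algorithm", "wf_algorithm"))
}

#' @param condition A [condition_on()] predicate.
#' @param label Label returned when the condition holds.
#' @rdname logical_algorithm
#' @export
rule <- function(condition, label) list(condition = condition, label = label)

#' Algorithm results
#'
#' Every algorithm returns a result carrying the headline `value` (score,
#' label or probability), a per-factor or per-feature `breakdown`, and a
#' `context` payload cached for rendering. For score algorithms the value
#' always equals the sum of the satisfied factors' weights in the breakdown.
#'
#' @param value Score, label or probability.
#' @param label Optional categorical reading of the value (e.g. a severity
#'   band or predicted class).
#' @param breakdown A data.frame of per-factor/per-feature contributions.
#' @param context Named list of pre-computed rendering payload.
#' @param algorithm Name of the producing algorithm.
#' @return A `wf_result`.
#' @export
algorithm_result <- function(value, label = NULL, breakdown = NULL,
                             context = list(), algorithm = NULL) {
  structure(list(value = value, label = label, breakdown = breakdown,
                 context = context, algorithm = algorithm),
            class = "wf_result")
}

#' @export
print.wf_result <- function(x, ...) {
  cat(sprintf("<wf_result> %s: value=%s%s\n", x$algorithm %||% "?",
              format(x$value),
              if (!is.null(x$label)) sprintf(" label=%s", x$label) else ""))
  if (!is.null(x$breakdown)) print(x$breakdown)
  invisible(x)
}

#' Run an algorithm on a single record
#'
#' The record is validated against the algorithm's schema first; validation
#' failures (missing required fields, out-of-range values) propagate as
#' structured conditions so the engine can pause a journey rather than
#' crash.
#'
#' @param algo A score, logical or predictive algorithm.
#' @param record A flat named list of input values.
#' @param ... Passed to methods.
#' @return A [algorithm_result()].
#' @export
run_algorithm <- function(algo, record, ...) UseMethod("run_algorithm")

#' @export
run_algorithm.wf_score_algorithm <- function(algo, record, ...) {
  rec <- validate_record(algo$schema, record)
  sat <- vapply(algo$factors, factor_satisfied, logical(1), record = rec)
  w <- vapply(algo$factors, `[[`, integer(1), "weight")
  breakdown <- data.frame(
    factor = vapply(algo$factors, `[[`, character(1), "name"),
    satisfied = sat,
    weight = w,
    points = ifelse(sat, w, 0L),
    stringsAsFactors = FALSE
  )
  algorithm_result(value = sum(breakdown$points), breakdown = breakdown,
                   context = list(max_score = algo$output_range[2]),
                   algorithm = algo$name)
}

#' @export
run_algorithm.wf_logical_algorithm <- function(algo, record, ...) {
  rec <- validate_record(algo$schema, record)
  label <- algo$default_label
  matched <- NA_character_
  for (r in algo$rules) {
    if (eval_condition(r$condition, rec)) {
      label <- r$label
      matched <- r$condition$field
      break
    }
  }
  algorithm_result(value = label, label = label,
                   context = list(matched_on = matched),
                   algorithm = algo$name)
}

# ---- CURB65 -----------------------------------------------------------------

#' The CURB65 severity score and NHS severity banding
#'
#' CURB65 awards one point for each of: mental confusion; blood urea above
#' 7 mmol/L; respiratory rate of 30 breaths/min or more; low blood pressure
#' (systolic below 90 mmHg or diastolic at or below 60 mmHg); and age 65 or
#' over. `curb65_score()` computes the 0-5 score with a per-factor
#' breakdown; `stratify_severity()` maps a score to the NHS band
#' (Low = 0-1, Moderate = 2, High = 3-5); `curb65_algorithm()` packages the
#' score as a reusable [score_algorithm()]. Cut-offs are overridable via
#' `cutoffs` for local guideline variants.
#'
#' @param confusion Logical; new mental confusion present.
#' @param urea Blood urea, mmol/L.
#' @param resp_rate Respiratory rate, breaths/min.
#' @param systolic_bp,diastolic_bp Blood pressure, mmHg.
#' @param age Age in years.
#' @param cutoffs Named list overriding any of `urea`, `resp_rate`,
#'   `systolic_bp`, `diastolic_bp`, `age`.
#' @return `curb65_score()`: a [algorithm_result()] with integer `value` in
#'   0-5 and a 5-row breakdown. `stratify_severity()`: one of `"Low"`,
#'   `"Moderate"`, `"High"`.
#' @export
#' @examples
#' curb65_score(TRUE, urea = 8, resp_rate = 32, systolic_bp = 85,
#'              diastolic_bp = 60, age = 70)$value  # 5
#' stratify_severity(2)  # "Moderate"
curb65_score <- function(confusion, urea, resp_rate, systolic_bp,
                         diastolic_bp, age, cutoffs = list()) {
  record <- list(confusion = confusion, urea = urea, resp_rate = resp_rate,
                 systolic_bp = systolic_bp, diastolic_bp = diastolic_bp,
                 age = age)
  run_algorithm(curb65_algorithm(cutoffs = cutoffs), record)
}

curb65_cutoffs <- function(cutoffs = list()) {
  utils::modifyList(
    list(urea = 7, resp_rate = 30, systolic_bp = 90, diastolic_bp = 60,
         age = 65),
    cutoffs
  )
}

#' @rdname curb65_score
#' @export
curb65_schema <- function() {
  data_schema("curb65_input", list(
    data_field("confusion", "boolean", required = TRUE),
    data_field("urea", "number", unit = "mmol/L", required = TRUE,
               range = c(0, 100)),
    data_field("resp_rate", "number", unit = "breaths/min", required = TRUE,
               range = c(0, 80)),
    data_field("systolic_bp", "number", unit = "mmHg", required = TRUE,
               range = c(0, 300)),
    data_field("diastolic_bp", "number", unit = "mmHg", required = TRUE,
               range = c(0, 200)),
    data_field("age", "integer", unit = "years", required = TRUE,
               range = c(0, 130))
  ), version = "1")
}

#' @rdname curb65_score
#' @export
curb65_algorithm <- function(cutoffs = list()) {
  co <- curb65_cutoffs(cutoffs)
  score_algorithm("curb65", curb65_schema(), list(
    risk_factor("confusion", condition_on("confusion", "is_true")),
    risk_factor("urea", condition_on("urea", ">", co$urea)),
    risk_factor("resp_rate", condition_on("resp_rate", ">=", co$resp_rate)),
    risk_factor("blood_pressure", list(
      condition_on("systolic_bp", "<", co$systolic_bp),
      condition_on("diastolic_bp", "<=", co$diastolic_bp)), combine = "any"),
    risk_factor("age", condition_on("age", ">=", co$age))
  ))
}

#' @rdname curb65_score
#' @export
severity_bands <- function() c("Low", "Moderate", "High")

#' @param score Integer CURB65 score, 0-5.
#' @rdname curb65_score
#' @export
stratify_severity <- function(score) {
  if (length(score) != 1L || is.na(score) || score != round(score) ||
      score < 0 || score > 5)
    abort_invalid_value("score", "CURB65 score must be an integer in 0..5")
  if (score <= 1) "Low" else if (score == 2) "Moderate" else "High"
}

severity_rank <- function(band) match(band, severity_bands())
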