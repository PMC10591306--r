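#' The community-acquired pneumonia management plan
#'
#' The reference plan shipped with the package: a triage step classifies
#' the admission from its primary ICD-10 code (via an on-the-fly transform
#' deriving the three-character category); CAP admissions cycle hourly
#' through a CURB65 assessment whose banded decision routes to a
#' Low/Moderate/High severity state step and back; non-CAP admissions end
#' at a terminal step; discharge finalises the journey. The severity band
#' and score are written to plan states before each advance.
#'
#' @param cutoffs CURB65 cut-off overrides (see [curb65_algorithm()]).
#' @param cap_codes ICD-10 category prefixes counted as CAP.
#' @return A checked [plan()].
#' @export
cap_plan <- function(cutoffs = list(), cap_codes = cap_code_set()) {
  demog_icd <- data_source(
    "demographics_icd",
    data_schema("admission_coding",
                list(data_field("primary_icd", "text", required = TRUE),
                     data_field("icd_prefix", "text")), version = "1"),
    transforms = list(builtin_transforms()$icd_prefix3))
  triage_input <- data_source(
    "triage_input",
    data_schema("triage", list(data_field("icd_prefix", "text",
                                          required = TRUE)), version = "1"),
    constituents = list(demog_icd))
  cap_check <- logical_algorithm(
    "cap_check", triage_input$schema,
    list(rule(condition_on("icd_prefix", "in", cap_codes), "cap")),
    default_label = "not_cap")

  demog_age <- data_source(
    "demographics_age",
    data_schema("demographics", list(
      data_field("age", "integer", unit = "years", required = TRUE)),
      version = "1"))
  vitals <- data_source(
    "vitals",
    data_schema("vitals", list(
      data_field("confusion", "boolean", required = TRUE),
      data_field("resp_rate", "number", unit = "breaths/min", required = TRUE),
      data_field("systolic_bp", "number", unit = "mmHg", required = TRUE),
      data_field("diastolic_bp", "number", unit = "mmHg", required = TRUE)),
      version = "1"))
  bloods <- data_source(
    "bloods",
    data_schema("bloods", list(
      data_field("urea", "number", unit = "mmol/L", required = TRUE)),
      version = "1"))
  curb_input <- data_source("curb65_input", curb65_schema(),
                            constituents = list(demog_age, vitals, bloods))

  plan(
    "cap_management",
    steps = list(
      step("triage", input = triage_input, algorithm = cap_check,
           decision = decision(c(cap = "assess", not_cap = "no_cap"),
                               selector_label())),
      step("assess", input = curb_input,
           algorithm = curb65_algorithm(cutoffs = cutoffs),
           decision = decision(c(Low = "low_severity",
                                 Moderate = "moderate_severity",
                                 High = "high_severity"),
                               selector_band()),
           actions = list(
             action_set_state("on_result", "curb65", from = "value"),
             action_set_state("on_decision_made", "severity",
                              from = "decision"))),
      step("low_severity", next_step = "assess"),
      step("moderate_severity", next_step = "assess"),
      step("high_severity", next_step = "assess"),
      step("no_cap", terminal = TRUE),
      step("discharged", terminal = TRUE)
    ),
    start = "triage",
    states = c("curb65", "severity"),
    on_discharge = "discharged"
  )
}

# Named record-level transforms referenced by name from plan config files.
builtin_transforms <- function() {
  list(
    icd_prefix3 = function(record) {
      if (!is.null(record$primary_icd))
        record$icd_prefix <- substr(record$primary_icd, 1, 3)
      record
    },
    parse_datetimes = function(record) {
      for (nm in names(record)) {
        if (grepl("(_at|_datetime|_time)$", nm) && is.character(record[[nm]]))
          record[[nm]] <- parse_time(record[[nm]])
      }
      record
    }
  )
}

#' Read a plan from a single configuration document
#'
#' Plans can be declared in one structured text (YAML) document rather
#' than host-language code, so the evaluation and service configurations
#' share a definition. The document has top-level keys `plan` (name,
#' start, states, on_discharge), `schemas`, `sources`, `algorithms` and
#' `steps`; `transforms` entries name built-in record transforms, and
#' predictive algorithms reference a [save_algorithm()] artefact by path.
#' See `system.file("extdata", "cap_plan.yaml", package = "wardflow")` for
#' a complete example.
#'
#' @param path Path to the YAML plan document.
#' @param artefact_dir Directory predictive-algorithm artefact paths are
#'   resolved against (defaults to the document's directory).
#' @return A [plan()].
#' @export
read_plan <- function(path, artefact_dir = dirname(path)) {
  doc <- yaml::read_yaml(path)
  tr <- builtin_transforms()

  schemas <- list()
  for (nm in names(doc$schemas %||% list())) {
    sc <- doc$schemas[[nm]]
    schemas[[nm]] <- data_schema(nm, lapply(sc$fields, function(f)
      data_field(f$name, f$kind %||% "number", unit = f$unit,
                 required = isTRUE(f$required), default = f$default,
                 range = if (!is.null(f$range)) as.numeric(unlist(f$range)),
                 choices = if (!is.null(f$choices)) as.character(unlist(f$choices)))),
      version = sc$version %||% "1")
  }
  get_schema <- function(nm) schemas[[nm]] %||%
    wf_abort("wf_config_error", sprintf("unknown schema '%s'", nm))

  sources <- list()
  build_source <- function(nm) {
    if (!is.null(sources[[nm]])) return(sources[[nm]])
    sp <- doc$sources[[nm]] %||%
      wf_abort("wf_config_error", sprintf("unknown source '%s'", nm))
    kids <- lapply(sp$constituents %||% list(), build_source)
    fns <- lapply(sp$transforms %||% list(), function(t)
      tr[[t]] %||% wf_abort("wf_config_error",
                            sprintf("unknown transform '%s'", t)))
    s <- data_source(nm, get_schema(sp$schema), transforms = fns,
                     constituents = kids)
    sources[[nm]] <<- s
    s
  }

  parse_condition <- function(c)
    condition_on(c$field, c$op %||% "is_true",
                 if (!is.null(c$value)) unlist(c$value))

  algos <- list()
  for (nm in names(doc$algorithms %||% list())) {
    ap <- doc$algorithms[[nm]]
    algos[[nm]] <- switch(
      ap$type,
      curb65 = curb65_algorithm(cutoffs = ap$cutoffs %||% list()),
      score = score_algorithm(nm, get_schema(ap$schema), lapply(
        ap$factors, function(f)
          risk_factor(f$name, lapply(f$conditions, parse_condition),
                      combine = f$combine %||% "any",
                      weight = f$weight %||% 1L))),
      logical = logical_algorithm(nm, get_schema(ap$schema), lapply(
        ap$rules, function(r) rule(parse_condition(r$condition), r$label)),
        default_label = ap$default_label),
      predictive = load_algorithm(file.path(artefact_dir, ap$artefact)),
      wf_abort("wf_config_error",
               sprintf("unknown algorithm type '%s'", ap$type))
    )
  }

  steps <- lapply(names(doc$steps), function(nm) {
    sp <- doc$steps[[nm]]
    dec <- NULL
    if (!is.null(sp$decision)) {
      sel <- sp$decision$selector %||% "label"
      selector <- if (is.list(sel) && !is.null(sel$constant))
        selector_constant(sel$constant)
      else switch(sel, band = selector_band(), label = selector_label(),
                  wf_abort("wf_config_error",
                           sprintf("unknown selector '%s'", sel)))
      dec <- decision(unlist(sp$decision$options), selector)
    }
    acts <- lapply(sp$actions %||% list(), function(a)
      action_set_state(a$trigger, a$state,
                       from = if (!is.null(a$constant))
                         list(constant = a$constant) else a$from %||% "value"))
    step(nm,
         input = if (!is.null(sp$input)) build_source(sp$input),
         algorithm = if (!is.null(sp$algorithm)) algos[[sp$algorithm]] %||%
           wf_abort("wf_config_error",
                    sprintf("unknown algorithm '%s'", sp$algorithm)),
         decision = dec, actions = acts,
         terminal = isTRUE(sp$terminal), next_step = sp$next_step)
  })

  plan(doc$plan$name %||% "plan", steps, start = doc$plan$start,
       states = as.character(unlist(doc$plan$states %||% list())),
       on_discharge = doc$plan$on_discharge)
}
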