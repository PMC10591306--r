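# Algorithm artefacts: one JSON document holding the schema, the
# algorithm's parameters, cached metadata, the model blob (base64-encoded
# raw bytes; xgboost boosters use the library's own raw format so artefacts
# survive library upgrades better than R serialization would) and a format
# version. Loading verifies the format version and, when the caller states
# the schema version its data conforms to, that it matches the artefact's.

ARTEFACT_FORMAT <- "wardflow-algorithm/1"

schema_to_list <- function(schema) {
  list(name = schema$name, version = schema$version,
       fields = lapply(unname(schema$fields), function(f) {
         Filter(Negate(is.null),
                list(name = f$name, kind = f$kind, unit = f$unit,
                     required = f$required, default = f$default,
                     range = f$range, choices = f$choices))
       }))
}

schema_from_list <- function(x) {
  data_schema(x$name, lapply(x$fields, function(f) {
    data_field(f$name, f$kind, unit = f$unit,
               required = isTRUE(f$required), default = f$default,
               range = if (!is.null(f$range)) as.numeric(f$range),
               choices = if (!is.null(f$choices)) as.character(f$choices))
  }), version = x$version)
}

condition_to_list <- function(cond)
  Filter(Negate(is.null),
         list(field = cond$field, op = cond$op, value = cond$value))

condition_from_list <- function(x)
  condition_on(x$field, x$op, if (!is.null(x$value)) unlist(x$value))

#' Save and load algorithm artefacts
#'
#' `save_algorithm()` writes a self-contained artefact (schema, parameters,
#' cached metadata, opaque model blob, format version) to a single JSON
#' file; `load_algorithm()` restores it. The round trip preserves
#' behaviour: scoring an identical record before and after gives an
#' identical result. On load the artefact's schema version can be checked
#' against the version the caller's data conforms to; a mismatch raises a
#' schema-mismatch error rather than silently scoring incompatible data.
#'
#' @param algo A score, logical or predictive algorithm.
#' @param path File path of the artefact (JSON).
#' @param expect_schema_version If non-`NULL`, the schema version the
#'   supplied data conforms to; compared by exact string match.
#' @return `load_algorithm()` returns the restored algorithm.
#' @export
save_algorithm <- function(algo, path) {
  doc <- list(format = ARTEFACT_FORMAT,
              type = class(algo)[1],
              name = algo$name,
              schema = schema_to_list(algo$schema))
  if (inherits(algo, "wf_score_algorithm")) {
    doc$params <- list(factors = lapply(algo$factors, function(f) {
      list(name = f$name, combine = f$combine, weight = f$weight,
           conditions = lapply(f$conditions, condition_to_list))
    }))
  } else if (inherits(algo, "wf_logical_algorithm")) {
    doc$params <- list(
      rules = lapply(algo$rules, function(r)
        list(condition = condition_to_list(r$condition), label = r$label)),
      default_label = algo$default_label)
  } else if (inherits(algo, "wf_predictive_algorithm")) {
    doc$params <- list(
      threshold = algo$threshold,
      classes = as.list(algo$classes),
      features = algo$encoder$features,
      stats = algo$encoder$stats,
      model_kind = model_kind(algo$model),
      model_blob = jsonlite::base64_enc(model_to_raw(algo$model)))
  } else {
    wf_abort("wf_config_error", "unsupported algorithm class")
  }
  if (!is.null(algo$metadata)) doc$metadata <- unclass(algo$metadata)
  # I(17) significant digits: doubles (cached metrics, thresholds, stats)
  # survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_algorithm
#' @export
load_algorithm <- function(path, expect_schema_version = NULL) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, ARTEFACT_FORMAT))
    abort_schema_mismatch(sprintf("unrecognised artefact format '%s'",
                                  doc$format %||% "<none>"))
  schema <- schema_from_list(doc$schema)
  if (!is.null(expect_schema_version) &&
      !identical(schema$version, as.character(expect_schema_version)))
    abort_schema_mismatch(sprintf(
      "artefact schema version '%s' does not match supplied data version '%s'",
      schema$version, expect_schema_version))
  p <- doc$params
  algo <- switch(
    doc$type,
    wf_score_algorithm = score_algorithm(doc$name, schema, lapply(
      p$factors, function(f)
        risk_factor(f$name, lapply(f$conditions, condition_from_list),
                    combine = f$combine, weight = f$weight))),
    wf_logical_algorithm = logical_algorithm(doc$name, schema, lapply(
      p$rules, function(r)
        rule(condition_from_list(r$condition), r$label)),
      default_label = p$default_label),
    wf_predictive_algorithm = {
      stats_df <- if (!is.null(p$stats))
        as.data.frame(lapply(
          stats::setNames(names(p$stats[[1]]), names(p$stats[[1]])),
          function(col) unlist(lapply(p$stats, `[[`, col))))
      model <- model_from_raw(p$model_kind, jsonlite::base64_dec(p$model_blob))
      predictive_algorithm(
        doc$name, schema,
        feature_encoder(unlist(p$features), stats = stats_df),
        model, threshold = p$threshold,
        classes = unlist(p$classes))
    },
    wf_abort("wf_config_error", sprintf("unknown algorithm type '%s'", doc$type))
  )
  if (!is.null(doc$metadata)) {
    m <- doc$metadata
    md <- model_metadata(m$auc, m$sensitivity, m$specificity, m$accuracy,
                         m$positive_predictive_value,
                         computed_on = m$computed_on,
                         cached = isTRUE(m$cached))
    if (inherits(algo, "wf_predictive_algorithm")) algo <- with_metadata(algo, md)
    else algo$metadata <- md
  }
  algo
}

model_kind <- function(model) {
  if (inherits(model, "xgb.Booster")) "xgboost" else "rds"
}

model_to_raw <- function(model) {
  if (inherits(model, "xgb.Booster")) xgboost::xgb.save.raw(model)
  else serialize(model, NULL)
}

model_from_raw <- function(kind, bytes) {
  if (identical(kind, "xgboost")) xgboost::xgb.load.raw(bytes)
  else unserialize(bytes)
}
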