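#' Predictive algorithm: a wrapped binary classifier
#'
#' The third algorithm modality wraps a previously trained, serializable
#' binary classifier together with the schema its inputs must satisfy, an
#' encoder turning a validated record into the model's feature vector, and
#' a probability threshold for the positive class. The canonical use is
#' in-hospital/30-day mortality prediction, with classes
#' `LikelySurvival` / `LikelyMortality`; a probability at or above the
#' threshold maps to the positive class (`>=` at the boundary).
#'
#' @param name Algorithm identifier.
#' @param schema Input [data_schema()].
#' @param encoder A [feature_encoder()].
#' @param model A fitted classifier: an `xgb.Booster`, a binomial `glm`, a
#'   `function(matrix) probabilities`, or [constant_model()].
#' @param threshold Probability cut for the positive class, in (0, 1).
#' @param classes Length-2 named character vector
#'   `c(negative = ..., positive = ...)`.
#' @param metadata Optional [model_metadata()] to cache with the algorithm.
#' @return A `wf_predictive_algorithm`.
#' @export
predictive_algorithm <- function(name, schema, encoder, model,
                                 threshold = 0.5,
                                 classes = c(negative = "LikelySurvival",
                                             positive = "LikelyMortality"),
                                 metadata = NULL) {
  stopifnot(inherits(schema, "wf_schema"), inherits(encoder, "wf_encoder"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    wf_abort("wf_config_error", "threshold must lie strictly in (0, 1)")
  missing_fields <- setdiff(encoder$features, schema_field_names(schema))
  if (length(missing_fields))
    abort_schema_mismatch(sprintf(
      "encoder features absent from schema: %s",
      paste(missing_fields, collapse = ", ")))
  n_model <- model_n_features(model)
  if (!is.na(n_model) && n_model != length(encoder$features))
    abort_schema_mismatch(sprintf(
      "encoder produces %d features but the model expects %d",
      length(encoder$features), n_model))
  structure(list(name = name, schema = schema, encoder = encoder,
                 model = model, threshold = threshold, classes = classes,
                 metadata = metadata),
            class = c("wf_predictive_algorithm", "wf_algorithm"))
}

#' Feature encoder for predictive algorithms
#'
#' Maps a validated record to the model's numeric feature vector: declared
#' fields are taken in order, with booleans encoded 0/1. `stats` carries
#' per-feature means and standard deviations from the training data; the
#' local explainer uses the standard deviations as perturbation scales.
#'
#' @param features Character vector of schema field names, in model input
#'   order.
#' @param stats Optional data.frame with columns `feature`, `mean`, `sd`.
#' @return A `wf_encoder`.
#' @export
feature_encoder <- function(features, stats = NULL) {
  structure(list(features = features, stats = stats), class = "wf_encoder")
}

encode_record <- function(encoder, record) {
  x <- vapply(encoder$features, function(f) {
    v <- record[[f]]
    if (is.null(v)) abort_missing_field(f)
    as.numeric(v)
  }, numeric(1))
  names(x) <- encoder$features
  x
}

#' A classifier stub returning a fixed probability
#'
#' Useful for wiring and boundary tests of decision logic.
#'
#' @param p Constant positive-class probability.
#' @export
constant_model <- function(p) structure(list(p = p), class = "wf_constant_model")

# Positive-class probability for a matrix of encoded rows.
predict_prob <- function(model, X) UseMethod("predict_prob")

#' @export
predict_prob.wf_constant_model <- function(model, X) rep(model$p, nrow(X))

#' @export
predict_prob.xgb.Booster <- function(model, X) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(X)))
}

#' @export
predict_prob.glm <- function(model, X) {
  as.numeric(stats::predict(model, newdata = as.data.frame(X),
                            type = "response"))
}

#' @export
predict_prob.function <- function(model, X) as.numeric(model(X))

model_n_features <- function(model) {
  if (inherits(model, "xgb.Booster")) {
    nf <- tryCatch(model$nfeatures, error = function(e) NULL)
    if (!is.null(nf)) return(as.integer(nf))
  }
  NA_integer_
}

#' @export
run_algorithm.wf_predictive_algorithm <- function(algo, record, ...) {
  rec <- validate_record(algo$schema, record)
  x <- encode_record(algo$encoder, rec)
  p <- predict_prob(algo$model, matrix(x, nrow = 1,
                                       dimnames = list(NULL, names(x))))
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    abort_schema_mismatch("model did not return a single probability in [0, 1]")
  label <- unname(if (p >= algo$threshold) algo$classes[["positive"]]
                  else algo$classes[["negative"]])
  breakdown <- data.frame(feature = names(x), value = unname(x),
                          stringsAsFactors = FALSE)
  algorithm_result(
    value = p, label = label, breakdown = breakdown,
    context = list(threshold = algo$threshold,
                   probabilities = stats::setNames(
                     c(1 - p, p), unname(algo$classes[c("negative", "positive")]))),
    algorithm = algo$name)
}

# ---- performance metadata ---------------------------------------------------

#' Model performance metadata
#'
#' Headline performance indicators cached alongside a predictive algorithm
#' so dashboards can render them without touching the model: area under the
#' ROC curve, and sensitivity, specificity, accuracy and positive
#' predictive value at the algorithm's threshold.
#'
#' @param auc,sensitivity,specificity,accuracy,positive_predictive_value
#'   Metrics in `[0, 1]`.
#' @param computed_on Free-text tag naming the data set used.
#' @param cached Whether the values were pre-computed and stored.
#' @return A `wf_model_metadata`.
#' @export
model_metadata <- function(auc, sensitivity, specificity, accuracy,
                           positive_predictive_value,
                           computed_on = "unspecified", cached = FALSE) {
  vals <- c(auc = auc, sensitivity = sensitivity, specificity = specificity,
            accuracy = accuracy,
            positive_predictive_value = positive_predictive_value)
  bad <- names(vals)[!is.na(vals) & (vals < 0 | vals > 1)]
  if (length(bad))
    abort_invalid_value(bad[1], "performance metrics must lie in [0, 1]")
  structure(c(as.list(vals),
              list(computed_on = computed_on, cached = cached)),
            class = "wf_model_metadata")
}

#' @export
print.wf_model_metadata <- function(x, ...) {
  cat(sprintf(
    "<wf_model_metadata> (%s)\n  AUC %.3f | sens %.3f | spec %.3f | acc %.3f | PPV %.3f\n",
    x$computed_on, x$auc, x$sensitivity, x$specificity, x$accuracy,
    x$positive_predictive_value))
  invisible(x)
}

confusion_metrics <- function(tp, fp, tn, fn) {
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       positive_predictive_value = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
}

#' Compute performance metadata for a predictive algorithm
#'
#' Scores every labelled record, thresholds at the algorithm's cut, and
#' derives sensitivity, specificity, accuracy and PPV from the confusion
#' counts; AUC comes from the ROC over the raw probabilities. Both classes
#' must be present, otherwise the AUC is undefined and a degenerate-labels
#' error is raised.
#'
#' @param algo A [predictive_algorithm()].
#' @param records A data.frame (one record per row) or list of records.
#' @param labels Logical/0-1 vector of observed positive-class outcomes.
#' @param computed_on Tag recorded in the metadata.
#' @return A [model_metadata()] with `cached = TRUE`.
#' @export
compute_metadata <- function(algo, records, labels,
                             computed_on = "training data") {
  if (is.data.frame(records))
    records <- lapply(seq_len(nrow(records)),
                      function(i) as.list(records[i, , drop = FALSE]))
  if (length(records) == 0L)
    wf_abort("wf_config_error", "no labelled records supplied")
  labels <- as.logical(labels)
  if (length(labels) != length(records))
    wf_abort("wf_config_error", "one label per record is required")
  if (length(unique(labels)) < 2L)
    wf_abort("wf_degenerate_labels",
             "both outcome classes are required to compute the AUC")
  X <- do.call(rbind, lapply(records, function(r)
    encode_record(algo$encoder, validate_record(algo$schema, r))))
  p <- predict_prob(algo$model, X)
  pred <- p >= algo$threshold
  cm <- confusion_metrics(tp = sum(pred & labels), fp = sum(pred & !labels),
                          tn = sum(!pred & !labels), fn = sum(!pred & labels))
  auc <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = p,
                                        levels = c(FALSE, TRUE),
                                        direction = "<", quiet = TRUE)))
  model_metadata(auc = auc, sensitivity = cm$sensitivity,
                 specificity = cm$specificity, accuracy = cm$accuracy,
                 positive_predictive_value = cm$positive_predictive_value,
                 computed_on = computed_on, cached = TRUE)
}

#' Attach cached metadata to an algorithm
#'
#' @param algo A [predictive_algorithm()].
#' @param metadata A [model_metadata()].
#' @export
with_metadata <- function(algo, metadata) {
  stopifnot(inherits(algo, "wf_predictive_algorithm"),
            inherits(metadata, "wf_model_metadata"))
  algo$metadata <- metadata
  algo
}

# ---- demonstration mortality model ------------------------------------------

#' Schema of the demonstration mortality model
#'
#' Per-admission aggregates of routinely collected values: age, worst blood
#' urea / C-reactive protein / respiratory rate over the stay, lowest
#' systolic blood pressure, and whether confusion was ever recorded. The
#' feature set is illustrative: it is chosen from the simulated admission
#' schema, not from any deployed hospital model.
#'
#' @export
mortality_schema <- function() {
  data_schema("mortality_input", list(
    data_field("age", "integer", unit = "years", required = TRUE),
    data_field("max_urea", "number", unit = "mmol/L", required = TRUE),
    data_field("max_crp", "number", unit = "mg/L", required = TRUE),
    data_field("max_resp_rate", "number", unit = "breaths/min", required = TRUE),
    data_field("min_systolic_bp", "number", unit = "mmHg", required = TRUE),
    data_field("any_confusion", "boolean", required = TRUE)
  ), version = "1")
}

#' Train the demonstration mortality classifier
#'
#' Fits a gradient-boosted tree classifier (xgboost) for in-hospital/30-day
#' mortality on per-admission feature rows such as those produced by
#' [mortality_features()], and returns it wrapped as a
#' [predictive_algorithm()] with cached performance metadata. This is a
#' demonstration model trained on synthetic cohorts only.
#'
#' @param features data.frame with the [mortality_schema()] columns.
#' @param died Logical outcome vector.
#' @param threshold Positive-class probability cut.
#' @param nrounds,max_depth,eta xgboost hyper-parameters.
#' @param seed Integer seed for the fit.
#' @return A `wf_predictive_algorithm` with cached metadata.
#' @export
train_mortality_model <- function(features, died, threshold = 0.5,
                                  nrounds = 40, max_depth = 3, eta = 0.3,
                                  seed = 1L) {
  schema <- mortality_schema()
  cols <- schema_field_names(schema)
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols))
    abort_schema_mismatch(sprintf("feature columns missing: %s",
                                  paste(missing_cols, collapse = ", ")))
  X <- as.matrix(data.frame(lapply(features[cols], as.numeric)))
  y <- as.numeric(as.logical(died))
  booster <- with_preserved_seed(seed, {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = nrounds, verbose = 0)
  })
  enc <- feature_encoder(cols, stats = data.frame(
    feature = cols, mean = apply(X, 2, mean), sd = apply(X, 2, stats::sd),
    row.names = NULL))
  algo <- predictive_algorithm("mortality", schema, enc, booster,
                               threshold = threshold)
  md <- compute_metadata(algo, as.data.frame(X), y,
                         computed_on = sprintf("synthetic cohort (n=%d)", nrow(X)))
  with_metadata(algo, md)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
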