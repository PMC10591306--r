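#' Local explanation of a single prediction
#'
#' Perturbation-based feature attribution for one record: the classifier is
#' queried on `n_perturbations` perturbed copies of the encoded record
#' (Gaussian noise scaled by each feature's training standard deviation;
#' 0/1-encoded features are flipped with probability 0.25), a locality
#' kernel `exp(-d^2 / width^2)` over the standardized distance `d` weights
#' the samples (width `0.75 * sqrt(n_features)`), and a weighted
#' ridge-regularized linear surrogate is fitted to the model's
#' probabilities. Each feature's signed contribution is its surrogate
#' coefficient multiplied by the feature's perturbation scale, i.e. the
#' local effect of a one-scale-unit change. Deterministic given `seed`.
#'
#' @param algo A [predictive_algorithm()].
#' @param record A record validating against the algorithm's schema.
#' @param n_perturbations Number of perturbed samples; must be at least the
#'   number of features.
#' @param seed Integer seed.
#' @param ridge Ridge penalty of the surrogate fit.
#' @return A `wf_explanation`: data.frame with columns `feature`, `value`
#'   (the record's encoded value) and `contribution`, in encoder order.
#' @export
#' @examples
#' algo <- predictive_algorithm(
#'   "demo",
#'   data_schema("s", list(data_field("x", "number", required = TRUE))),
#'   feature_encoder("x"),
#'   function(X) as.numeric(X[, 1] > 0))
#' explain_local(algo, list(x = 0.2), n_perturbations = 200, seed = 1)
explain_local <- function(algo, record, n_perturbations = 500, seed = 1L,
                          ridge = 1e-2) {
  stopifnot(inherits(algo, "wf_predictive_algorithm"))
  rec <- validate_record(algo$schema, record)
  x0 <- encode_record(algo$encoder, rec)
  p <- length(x0)
  if (n_perturbations < p)
    wf_abort("wf_insufficient_samples",
             sprintf("need at least %d perturbations for %d features", p, p))

  scales <- perturbation_scales(algo$encoder, x0)
  binary <- vapply(names(x0), function(f) {
    fld <- algo$schema$fields[[f]]
    !is.null(fld) && fld$kind == "boolean"
  }, logical(1))

  with_preserved_seed(seed, {
    X <- matrix(rep(x0, each = n_perturbations), nrow = n_perturbations,
                dimnames = list(NULL, names(x0)))
    for (j in seq_len(p)) {
      if (binary[j]) {
        flip <- stats::runif(n_perturbations) < 0.25
        X[flip, j] <- 1 - X[flip, j]
      } else {
        X[, j] <- X[, j] + stats::rnorm(n_perturbations, sd = scales[j])
      }
    }
    y <- predict_prob(algo$model, X)

    Z <- sweep(sweep(X, 2, x0, "-"), 2, scales, "/")   # standardized offsets
    d2 <- rowSums(Z^2)
    width <- 0.75 * sqrt(p)
    w <- exp(-d2 / width^2)

    # weighted ridge on standardized offsets, intercept unpenalized via
    # weighted centering
    wsum <- sum(w)
    zbar <- colSums(Z * w) / wsum
    ybar <- sum(y * w) / wsum
    Zc <- sweep(Z, 2, zbar, "-")
    yc <- y - ybar
    A <- crossprod(Zc, Zc * w) + diag(ridge, p)
    beta <- solve(A, crossprod(Zc, yc * w))[, 1]

    structure(
      data.frame(feature = names(x0), value = unname(x0),
                 contribution = unname(beta), stringsAsFactors = FALSE),
      class = c("wf_explanation", "data.frame"),
      seed = seed, n_perturbations = n_perturbations)
  })
}

# Perturbation scale per feature: training sd where the encoder carries
# stats (zero-variance features fall back to 1), else 1.
perturbation_scales <- function(encoder, x0) {
  scales <- rep(1, length(x0))
  names(scales) <- names(x0)
  st <- encoder$stats
  if (!is.null(st)) {
    idx <- match(names(x0), st$feature)
    ok <- !is.na(idx) & !is.na(st$sd[idx]) & st$sd[idx] > 0
    scales[ok] <- st$sd[idx[ok]]
  }
  scales
}
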