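#' The configured community-acquired pneumonia code set
#'
#' ICD-10 J12-J18 in primary diagnostic position at admission. The set is
#' a configurable argument everywhere it is used.
#'
#' @export
cap_code_set <- function() CAP_ICD_PREFIXES

#' Identify a community-acquired pneumonia admission from coded diagnoses
#'
#' `TRUE` iff the primary-position ICD-10 code's three-character category
#' is in the configured CAP code set.
#'
#' @param record Named list with `primary_icd` (or a non-empty `icd_codes`
#'   vector whose first element is the primary code).
#' @param cap_codes Character vector of ICD-10 category prefixes.
#' @return Logical flag.
#' @export
#' @examples
#' diagnose_cap(list(primary_icd = "J18.1"))  # TRUE
#' diagnose_cap(list(primary_icd = "I21.0"))  # FALSE
diagnose_cap <- function(record, cap_codes = cap_code_set()) {
  code <- record$primary_icd
  if (is.null(code) || length(code) == 0L || is.na(code) || !nzchar(code)) {
    codes <- record$icd_codes
    if (is.null(codes) || length(codes) == 0L)
      abort_missing_field("primary_icd")
    code <- codes[[1]]
  }
  substr(code, 1, 3) %in% cap_codes
}

#' Maximum severity over a journey
#'
#' The highest severity band recorded over an admission's hourly
#' evaluations, under the ordering Low < Moderate < High.
#'
#' @param journey A `wf_journey` from [run_replay()]/[run_live()], or a
#'   character vector of band labels.
#' @return One of `"Low"`, `"Moderate"`, `"High"`.
#' @export
max_severity <- function(journey) {
  bands <- if (inherits(journey, "wf_journey"))
    journey$states[["severity"]]$value
  else as.character(journey)
  bands <- bands[!is.na(bands)]
  if (length(bands) == 0L)
    wf_abort("wf_no_severity", "journey contains no severity results")
  bad <- setdiff(bands, severity_bands())
  if (length(bad))
    abort_invalid_value("severity", sprintf("unknown band '%s'", bad[1]))
  severity_bands()[max(severity_rank(bands))]
}

#' Link manual reviews to admissions
#'
#' A review matches an admission iff the patient IDs are equal and the
#' review's recorded admission datetime falls within the admission
#' interval extended by `tolerance_hours` on both sides. Matching is
#' one-to-one: admissions are taken in admission order and each takes its
#' earliest eligible unused review; a review eligible for several
#' admissions is kept by the first and a warning is logged.
#'
#' @param admissions data.frame with `admission_id`, `patient_id`,
#'   `admitted`, `discharged`.
#' @param reviews data.frame with `patient_id`, `admission_datetime` and
#'   review columns (e.g. `band`).
#' @param tolerance_hours Matching window half-width around the admission
#'   interval.
#' @return List: `matched` (admission columns + review columns),
#'   `unmatched_admissions`, `unmatched_reviews`.
#' @export
link_reviews <- function(admissions, reviews, tolerance_hours = 24) {
  tol <- tolerance_hours * 3600
  used <- rep(FALSE, nrow(reviews))
  ord <- order(admissions$admitted)
  match_idx <- rep(NA_integer_, nrow(admissions))
  multi <- 0L
  for (i in ord) {
    lo <- as.numeric(admissions$admitted[i]) - tol
    hi <- as.numeric(admissions$discharged[i]) + tol
    cand <- which(reviews$patient_id == admissions$patient_id[i] &
                    as.numeric(reviews$admission_datetime) >= lo &
                    as.numeric(reviews$admission_datetime) <= hi)
    if (length(cand) == 0L) next
    if (any(used[cand])) multi <- multi + length(intersect(which(used), cand))
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) next
    pick <- cand[order(reviews$admission_datetime[cand])][1]
    used[pick] <- TRUE
    match_idx[i] <- pick
  }
  if (multi > 0L)
    warning(sprintf("%d review(s) were eligible for more than one admission; first match kept",
                    multi))
  matched_rows <- which(!is.na(match_idx))
  matched <- cbind(admissions[matched_rows, , drop = FALSE],
                   reviews[match_idx[matched_rows], , drop = FALSE])
  rownames(matched) <- NULL
  list(matched = matched,
       unmatched_admissions = admissions[is.na(match_idx), , drop = FALSE],
       unmatched_reviews = reviews[!used, , drop = FALSE])
}

#' Severity cross-tabulation of reviewer versus engine bands
#'
#' Tallies the frequency of each (reviewer band, engine band) severity
#' pair into a 3x3 contingency table, with the agreement count on the
#' diagonal, the count of engine-High admissions under-scored by the
#' reviewer (engine High, reviewer Low/Moderate) and the count where the
#' reviewer's band exceeds the engine's.
#'
#' @param pairs data.frame with columns `reviewer_band` and `engine_band`.
#' @return A `wf_crosstab`.
#' @export
crosstab_severity <- function(pairs) {
  bands <- severity_bands()
  bad <- setdiff(stats::na.omit(unique(c(pairs$reviewer_band,
                                         pairs$engine_band))), bands)
  if (length(bad))
    abort_invalid_value("band", sprintf("unknown severity band '%s'", bad[1]))
  counts <- table(factor(pairs$reviewer_band, levels = bands),
                  factor(pairs$engine_band, levels = bands))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(reviewer = bands, engine = bands))
  n <- sum(counts)
  agreement <- sum(diag(counts))
  rk <- severity_rank(bands)
  over <- sum(counts[outer(rk, rk, ">")])
  structure(list(counts = counts, n = n, agreement = agreement,
                 agreement_fraction = if (n > 0) agreement / n else NA_real_,
                 engine_high_underscored = counts["Low", "High"] +
                   counts["Moderate", "High"],
                 reviewer_over_engine = over),
            class = "wf_crosstab")
}

#' @export
print.wf_crosstab <- function(x, ...) {
  cat("<wf_crosstab> reviewer (rows) x engine (cols)\n")
  print(x$counts)
  cat(sprintf("n=%d, agreement %d (%.1f%%), engine-High under-scored %d, reviewer>engine %d\n",
              x$n, x$agreement, 100 * (x$agreement_fraction %||% NA),
              x$engine_high_underscored, x$reviewer_over_engine))
  invisible(x)
}

#' Retrospective severity-comparison evaluation
#'
#' The full quality-improvement pipeline: identify CAP admissions from
#' their primary diagnosis code, replay the management plan hourly over
#' the store, take each journey's maximum severity band, link manual
#' reviews by patient ID and admission datetime, and cross-tabulate the
#' reviewer's single manual band against the engine's hourly maximum. The
#' report also splits CAP admissions into reviewed / not reviewed and
#' gives the engine severity distribution of the unreviewed group.
#'
#' @param store A replay store.
#' @param reviews Reviewer table (see [simulate_reviews()]).
#' @param plan The management plan; defaults to [cap_plan()].
#' @param cap_codes CAP ICD-10 category prefixes.
#' @param tolerance_hours Review-linkage window.
#' @param ... Engine options passed to [run_replay()].
#' @return A `wf_evaluation`: counts, percentages, the `wf_crosstab`, the
#'   engine-band distribution of unreviewed CAP admissions, and the
#'   underlying run.
#' @export
evaluate_severity <- function(store, reviews, plan = cap_plan(),
                              cap_codes = cap_code_set(),
                              tolerance_hours = 24, ...) {
  adm <- store$admissions
  is_cap <- vapply(seq_len(nrow(adm)), function(i)
    diagnose_cap(list(primary_icd = adm$primary_icd[i],
                      icd_codes = strsplit(adm$icd_codes[i] %||% "", ";")[[1]]),
                 cap_codes = cap_codes), logical(1))
  cap_adm <- adm[is_cap, , drop = FALSE]

  run <- run_replay(plan, store, ...)
  engine_band <- vapply(cap_adm$admission_id, function(id) {
    jn <- run$journeys[[id]]
    if (is.null(jn)) return(NA_character_)
    tryCatch(max_severity(jn), wf_no_severity = function(e) NA_character_)
  }, character(1))

  linked <- link_reviews(cap_adm, reviews, tolerance_hours = tolerance_hours)
  matched <- linked$matched
  n_reviewed <- nrow(matched)
  has_score <- !is.na(matched$band)
  pairs <- data.frame(
    admission_id = matched$admission_id[has_score],
    reviewer_band = matched$band[has_score],
    engine_band = engine_band[match(matched$admission_id[has_score],
                                    cap_adm$admission_id)],
    stringsAsFactors = FALSE)
  comparable <- !is.na(pairs$engine_band)
  xtab <- crosstab_severity(pairs[comparable, , drop = FALSE])

  unreviewed_ids <- setdiff(cap_adm$admission_id, matched$admission_id)
  unrev_band <- engine_band[match(unreviewed_ids, cap_adm$admission_id)]
  unreviewed_by_band <- vapply(severity_bands(), function(b)
    sum(unrev_band == b, na.rm = TRUE), integer(1))
  n_unrev_modhigh <- sum(unreviewed_by_band[c("Moderate", "High")])

  n_cap <- nrow(cap_adm)
  pct <- function(a, b) if (b > 0) 100 * a / b else NA_real_
  structure(list(
    n_admissions = nrow(adm),
    n_cap = n_cap,
    n_reviewed = n_reviewed,
    pct_reviewed = pct(n_reviewed, n_cap),
    n_with_reviewer_score = sum(has_score),
    pct_with_reviewer_score = pct(sum(has_score), n_reviewed),
    n_compared = xtab$n,
    crosstab = xtab,
    n_agree = xtab$agreement,
    pct_agree = 100 * xtab$agreement_fraction,
    n_engine_high_underscored = xtab$engine_high_underscored,
    pct_engine_high_underscored = pct(xtab$engine_high_underscored, xtab$n),
    n_reviewer_over_engine = xtab$reviewer_over_engine,
    n_not_reviewed = n_cap - n_reviewed,
    pct_not_reviewed = pct(n_cap - n_reviewed, n_cap),
    unreviewed_by_engine_band = unreviewed_by_band,
    n_unreviewed_moderate_high = n_unrev_modhigh,
    pct_unreviewed_moderate_high = pct(n_unrev_modhigh, n_cap - n_reviewed),
    engine_band = stats::setNames(engine_band, cap_adm$admission_id),
    run = run),
    class = "wf_evaluation")
}

#' @export
print.wf_evaluation <- function(x, ...) {
  cat(sprintf("<wf_evaluation> %d admissions, %d CAP\n", x$n_admissions,
              x$n_cap))
  cat(sprintf("  reviewed:     %d (%.1f%%), %d with a recorded score\n",
              x$n_reviewed, x$pct_reviewed, x$n_with_reviewer_score))
  cat(sprintf("  compared:     %d, agreement %d (%.1f%%)\n", x$n_compared,
              x$n_agree, x$pct_agree))
  cat(sprintf("  engine High under-scored by reviewer: %d\n",
              x$n_engine_high_underscored))
  cat(sprintf("  not reviewed: %d (%.1f%%), of which moderate/high %d (%.1f%%)\n",
              x$n_not_reviewed, x$pct_not_reviewed,
              x$n_unreviewed_moderate_high, x$pct_unreviewed_moderate_high))
  invisible(x)
}
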