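#' Configuration of the simulated admissions feed
#'
#' The simulator emulates a hospital data-warehouse feed: admission /
#' discharge / lab / vital / imaging / outcome events with the
#' record-and-field structure the engine expects, plus a ground-truth
#' table. Severity ground truth is enforced constructively: a CAP
#' admission's observations are sampled conditional on its target band so
#' that the hourly CURB65 maximum over the stay equals that band exactly.
#'
#' @param n_admissions Number of admissions to generate.
#' @param seed Integer seed; the stream is fully seed-deterministic.
#' @param cap_fraction Probability an admission is community-acquired
#'   pneumonia (coded J12-J18 in primary position).
#' @param severity_mix Probabilities over the `Low`/`Moderate`/`High`
#'   target bands for CAP admissions; must sum to 1.
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters
#'   (hours).
#' @param los_range Closed bounds on length of stay, hours.
#' @param panels_per_day Mean number of extra observation panels per day
#'   beyond the admission and severity-peak panels.
#' @param review_fraction Fraction of CAP admissions receiving a manual
#'   severity review.
#' @param reviewer_error Probability a simulated reviewer mis-bands
#'   severity by one level (see [simulate_reviews()]).
#' @param review_score_missing Fraction of reviews recorded without a
#'   usable CURB65 score.
#' @param start First possible admission instant.
#' @param horizon_days Admissions are spread uniformly over this window.
#' @return A `wf_sim_config`.
#' @export
sim_config <- function(n_admissions = 200, seed = 1L, cap_fraction = 0.5,
                       severity_mix = c(Low = 0.45, Moderate = 0.25,
                                        High = 0.30),
                       los_meanlog = log(72), los_sdlog = 0.4,
                       los_range = c(12, 240), panels_per_day = 2,
                       review_fraction = 0.45, reviewer_error = 0.3,
                       review_score_missing = 0.2,
                       start = as.POSIXct("2022-04-01 00:00:00", tz = "UTC"),
                       horizon_days = 30) {
  if (n_admissions < 1)
    wf_abort("wf_config_error", "n_admissions must be at least 1")
  if (abs(sum(severity_mix) - 1) > 1e-8 || any(severity_mix < 0))
    wf_abort("wf_config_error", "severity_mix must be probabilities summing to 1")
  if (!setequal(names(severity_mix), severity_bands()))
    wf_abort("wf_config_error", "severity_mix must name Low, Moderate, High")
  if (cap_fraction < 0 || cap_fraction > 1 ||
      review_fraction < 0 || review_fraction > 1 ||
      reviewer_error < 0 || reviewer_error > 1)
    wf_abort("wf_config_error", "fractions must lie in [0, 1]")
  if (los_range[1] < 2)
    wf_abort("wf_config_error",
             "length of stay must allow at least two hourly assessments")
  structure(list(n_admissions = as.integer(n_admissions),
                 seed = as.integer(seed),
                 cap_fraction = cap_fraction,
                 severity_mix = severity_mix[severity_bands()],
                 los_meanlog = los_meanlog, los_sdlog = los_sdlog,
                 los_range = los_range, panels_per_day = panels_per_day,
                 review_fraction = review_fraction,
                 reviewer_error = reviewer_error,
                 review_score_missing = review_score_missing,
                 start = start, horizon_days = horizon_days),
            class = "wf_sim_config")
}

CAP_ICD_PREFIXES <- c("J12", "J13", "J14", "J15", "J16", "J17", "J18")
CAP_ICD_CODES <- c("J12.9", "J13", "J14", "J15.9", "J16.8", "J18.0",
                   "J18.1", "J18.9")
OTHER_ICD_CODES <- c("I21.0", "I50.0", "N39.0", "K92.2", "E11.9", "C34.9",
                     "I63.9", "A41.9")

# CURB65 factor names in plan order; "age" is constant over an admission,
# the others are observation-driven.
CURB_FACTORS <- c("confusion", "urea", "resp_rate", "blood_pressure", "age")

# Observation values that do / do not trigger each factor. Triggering and
# safe draws sit clear of the clinical cut-offs so that carried-forward
# values can never flip a factor unintentionally.
safe_panel <- function() {
  list(confusion = FALSE,
       urea = round(stats::runif(1, 3.0, 6.5), 1),
       resp_rate = round(stats::runif(1, 14, 24)),
       systolic_bp = round(stats::runif(1, 105, 140)),
       diastolic_bp = round(stats::runif(1, 65, 85)))
}

trigger_values <- function(factors_on) {
  p <- safe_panel()
  if ("confusion" %in% factors_on) p$confusion <- TRUE
  if ("urea" %in% factors_on) p$urea <- round(stats::runif(1, 7.5, 24), 1)
  if ("resp_rate" %in% factors_on) p$resp_rate <- round(stats::runif(1, 30, 44))
  if ("blood_pressure" %in% factors_on) {
    p$systolic_bp <- round(stats::runif(1, 70, 88))
    p$diastolic_bp <- round(stats::runif(1, 40, 58))
  }
  p
}

band_to_n_factors <- function(band) {
  switch(band,
         Low = sample(0:1, 1),
         Moderate = 2L,
         High = sample(3:5, 1))
}

#' Generate a synthetic admission cohort with known ground truth
#'
#' Produces the message stream (ordered by timestamp) and a ground-truth
#' table. Every CAP admission is assigned a target severity band from
#' `severity_mix`; a set of CURB65 factors of the matching size is chosen,
#' observation panels are safe before a sampled peak hour and trigger
#' exactly the chosen factors from the peak onwards, and an observation
#' panel is emitted at admission and at the peak hour. By construction the
#' engine's hourly CURB65 maximum over the stay equals the target band.
#' Mortality is sampled with probability increasing in severity and age
#' (logistic link; illustrative only) and emitted as an outcome message at
#' discharge.
#'
#' @param cfg A [sim_config()].
#' @return List with `messages` (data.frame: `kind`, `admission_id`,
#'   `timestamp`, `payload` list-column) and `truth` (data.frame:
#'   `admission_id`, `patient_id`, `is_cap`, `true_max_severity`, `died`,
#'   `age`, `admitted`, `discharged`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "wf_sim_config"))
  with_preserved_seed(cfg$seed, {
    msgs <- list()
    truth <- list()
    t0 <- as.numeric(cfg$start)
    for (i in seq_len(cfg$n_admissions)) {
      id <- sprintf("A%05d", i)
      pid <- sprintf("P%05d", i)
      admitted <- t0 + floor(stats::runif(1, 0, cfg$horizon_days * 24)) * 3600
      los <- exp(stats::rnorm(1, cfg$los_meanlog, cfg$los_sdlog))
      los <- min(max(los, cfg$los_range[1]), cfg$los_range[2])
      los <- floor(los)                       # whole hours
      discharged <- admitted + los * 3600
      is_cap <- stats::runif(1) < cfg$cap_fraction
      sex <- sample(c("F", "M"), 1)

      if (is_cap) {
        band <- sample(severity_bands(), 1, prob = cfg$severity_mix)
        k <- band_to_n_factors(band)
        factors_on <- if (k > 0) sample(CURB_FACTORS, k) else character(0)
        age <- if ("age" %in% factors_on) sample(65:95, 1) else sample(16:64, 1)
        peak_hour <- if (los > 2) sample(seq_len(los - 1L), 1) else 1L
        primary <- sample(CAP_ICD_CODES, 1)
      } else {
        band <- NA_character_
        factors_on <- character(0)
        age <- sample(16:95, 1)
        peak_hour <- NA_integer_
        primary <- sample(OTHER_ICD_CODES, 1)
      }
      codes <- c(primary, sample(c("E87.6", "N17.9", "D64.9", "F05.9"),
                                 sample(0:2, 1)))

      push <- function(kind, ts, payload)
        msgs[[length(msgs) + 1L]] <<- message_event(
          kind, id, as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"), payload)

      push("admission", admitted,
           list(patient_id = pid, age = age, sex = sex,
                primary_icd = primary, icd_codes = as.list(codes)))

      crp_meanlog <- if (is_cap) log(40 + 50 * severity_rank(band)) else log(15)
      emit_panel <- function(ts, hot) {
        p <- if (hot) trigger_values(factors_on) else safe_panel()
        crp <- round(stats::rlnorm(1, crp_meanlog, 0.4), 1)
        push("vital", ts, list(confusion = p$confusion,
                               resp_rate = p$resp_rate,
                               systolic_bp = p$systolic_bp,
                               diastolic_bp = p$diastolic_bp))
        push("lab", ts, list(urea = p$urea, crp = crp))
      }

      if (is_cap) {
        emit_panel(admitted, hot = peak_hour == 0L)
        emit_panel(admitted + peak_hour * 3600, hot = TRUE)
        n_extra <- stats::rpois(1, cfg$panels_per_day * los / 24)
        if (n_extra > 0) {
          at <- admitted + stats::runif(n_extra, 0, los) * 3600
          for (ts in at) emit_panel(ts, hot = ts >= admitted + peak_hour * 3600)
        }
        push("imaging_report", admitted + 2 * 3600,
             list(modality = "CXR", flagged = TRUE,
                  text = "synthetic report: consolidation consistent with pneumonia"))
        p_die <- stats::plogis(-5 + 0.8 * (band == "Moderate") +
                                 2.2 * (band == "High") +
                                 0.03 * max(age - 65, 0))
      } else {
        emit_panel(admitted, hot = FALSE)
        p_die <- 0.02
      }
      died <- stats::runif(1) < p_die

      push("discharge", discharged, list(destination = if (died) "died"
                                         else "home"))
      push("outcome", discharged, list(died = died))

      truth[[i]] <- data.frame(
        admission_id = id, patient_id = pid, is_cap = is_cap,
        true_max_severity = band, died = died, age = age,
        admitted = as.POSIXct(admitted, origin = "1970-01-01", tz = "UTC"),
        discharged = as.POSIXct(discharged, origin = "1970-01-01", tz = "UTC"),
        stringsAsFactors = FALSE)
    }
    messages <- messages_df(msgs)
    messages <- messages[order(messages$timestamp), , drop = FALSE]
    rownames(messages) <- NULL
    truth <- do.call(rbind, truth)
    list(messages = messages, truth = truth)
  })
}

#' Simulate manual severity reviews
#'
#' A configurable fraction of CAP admissions receives one manually banded
#' CURB65 review. With probability `reviewer_error` the recorded band is
#' perturbed by one level: Moderate and High move down (emulating manual
#' under-scoring), Low moves up to Moderate (its only available
#' neighbour), so every error event changes the band. A fraction of
#' reviews carries no usable score (`band` is `NA`), mirroring service
#' records where the score was not recorded.
#'
#' @param truth Ground-truth table from [simulate_cohort()].
#' @param cfg The same [sim_config()].
#' @return data.frame: `patient_id`, `admission_datetime`, `band`,
#'   `curb65`, `review_time`.
#' @export
simulate_reviews <- function(truth, cfg) {
  stopifnot(inherits(cfg, "wf_sim_config"))
  with_preserved_seed(cfg$seed + 1L, {
    cap <- truth[truth$is_cap, , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(cap))) {
      if (stats::runif(1) >= cfg$review_fraction) next
      band <- cap$true_max_severity[i]
      if (stats::runif(1) < cfg$reviewer_error) {
        band <- switch(band, Low = "Moderate", Moderate = "Low",
                       High = "Moderate")
      }
      score <- switch(band, Low = sample(0:1, 1), Moderate = 2L,
                      High = sample(3:5, 1))
      if (stats::runif(1) < cfg$review_score_missing) {
        band <- NA_character_
        score <- NA_integer_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = cap$patient_id[i],
        admission_datetime = cap$admitted[i],
        band = band, curb65 = score,
        review_time = cap$admitted[i] + stats::runif(1, 1, 12) * 3600,
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
      return(data.frame(patient_id = character(),
                        admission_datetime = as.POSIXct(character(), tz = "UTC"),
                        band = character(), curb65 = integer(),
                        review_time = as.POSIXct(character(), tz = "UTC")))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Per-admission features for the demonstration mortality model
#'
#' Aggregates each admission's observations into the
#' [mortality_schema()] feature row: age, worst urea/CRP/respiratory rate,
#' lowest systolic blood pressure, any recorded confusion.
#'
#' @param store A replay store.
#' @return data.frame keyed by `admission_id` with the six feature columns.
#' @export
mortality_features <- function(store) {
  adm <- store$admissions
  obs <- store$observations
  num <- suppressWarnings(as.numeric(obs$value))
  agg <- function(field, fn, default) {
    vapply(adm$admission_id, function(id) {
      v <- num[obs$admission_id == id & obs$field == field]
      v <- v[!is.na(v)]
      if (length(v)) fn(v) else default
    }, numeric(1))
  }
  conf <- vapply(adm$admission_id, function(id) {
    v <- obs$value[obs$admission_id == id & obs$field == "confusion"]
    any(tolower(v) %in% c("true", "1"))
  }, logical(1))
  data.frame(admission_id = adm$admission_id, age = adm$age,
             max_urea = agg("urea", max, 5), max_crp = agg("crp", max, 10),
             max_resp_rate = agg("resp_rate", max, 18),
             min_systolic_bp = agg("systolic_bp", min, 120),
             any_confusion = conf, row.names = NULL,
             stringsAsFactors = FALSE)
}
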