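# Shared fixtures, built in code at test time.

bloods_schema <- function() {
  data_schema("bloods", list(
    data_field("urea", "number", unit = "mmol/L", required = TRUE),
    data_field("crp", "number", unit = "mg/L", default = 0)
  ))
}

# A tiny linear three-step plan: screen -> act -> done.
linear_plan <- function() {
  src <- data_source("vals", data_schema("vals", list(
    data_field("x", "number", required = TRUE))))
  algo <- logical_algorithm("screen_x", src$schema,
                            list(rule(condition_on("x", ">=", 10), "hit")),
                            default_label = "miss")
  plan("linear", list(
    step("screen", input = src, algorithm = algo,
         decision = decision(c(hit = "act", miss = "done"), selector_label())),
    step("act", next_step = "done"),
    step("done", terminal = TRUE)
  ), start = "screen")
}

# Independent CURB65 oracle: direct per-factor arithmetic, no shared code
# with the implementation.
curb65_oracle <- function(confusion, urea, resp_rate, systolic_bp,
                          diastolic_bp, age) {
  sum(isTRUE(confusion),
      urea > 7,
      resp_rate >= 30,
      systolic_bp < 90 || diastolic_bp <= 60,
      age >= 65)
}

# Inputs realising a given on/off combination of the five CURB65 factors.
curb65_inputs_for <- function(conf_on, urea_on, rr_on, bp_on, age_on) {
  list(confusion = conf_on,
       urea = if (urea_on) 9.0 else 5.0,
       resp_rate = if (rr_on) 34 else 18,
       systolic_bp = if (bp_on) 82 else 118,
       diastolic_bp = if (bp_on) 55 else 75,
       age = if (age_on) 78L else 50L)
}

# One hand-built admission store: CAP patient whose urea worsens over the
# stay, crossing the CURB65 threshold at hour 5.
worsening_store <- function() {
  t0 <- as.POSIXct("2022-04-03 08:00:00", tz = "UTC")
  adm <- data.frame(
    admission_id = "A1", patient_id = "P1", age = 70L, sex = "F",
    admitted = t0, discharged = t0 + 10 * 3600,
    primary_icd = "J18.1", icd_codes = "J18.1;E87.6",
    stringsAsFactors = FALSE)
  obs <- rbind(
    data.frame(admission_id = "A1", field = "confusion", value = "FALSE",
               timestamp = t0, stringsAsFactors = FALSE),
    data.frame(admission_id = "A1", field = "resp_rate", value = "18",
               timestamp = t0, stringsAsFactors = FALSE),
    data.frame(admission_id = "A1", field = "systolic_bp", value = "120",
               timestamp = t0, stringsAsFactors = FALSE),
    data.frame(admission_id = "A1", field = "diastolic_bp", value = "75",
               timestamp = t0, stringsAsFactors = FALSE),
    data.frame(admission_id = "A1", field = "urea", value = "5.0",
               timestamp = t0, stringsAsFactors = FALSE),
    # hour 5: urea crosses 7 mmol/L, confusion and low BP appear -> score 4
    data.frame(admission_id = "A1", field = "confusion", value = "TRUE",
               timestamp = t0 + 5 * 3600, stringsAsFactors = FALSE),
    data.frame(admission_id = "A1", field = "resp_rate", value = "33",
               timestamp = t0 + 5 * 3600, stringsAsFactors = FALSE),
    data.frame(admission_id = "A1", field = "systolic_bp", value = "85",
               timestamp = t0 + 5 * 3600, stringsAsFactors = FALSE),
    data.frame(admission_id = "A1", field = "diastolic_bp", value = "55",
               timestamp = t0 + 5 * 3600, stringsAsFactors = FALSE),
    data.frame(admission_id = "A1", field = "urea", value = "11.2",
               timestamp = t0 + 5 * 3600, stringsAsFactors = FALSE)
  )
  new_store(adm, obs)
}

# Small labelled data set a threshold-0.5 stub separates perfectly.
separable_records <- function(n_per_class = 10) {
  list(records = data.frame(x = c(seq(-1, -0.1, length.out = n_per_class),
                                  seq(0.1, 1, length.out = n_per_class))),
       labels = rep(c(FALSE, TRUE), each = n_per_class))
}

x_only_predictive <- function(model, threshold = 0.5) {
  predictive_algorithm(
    "demo",
    data_schema("s", list(data_field("x", "number", required = TRUE))),
    feature_encoder("x"),
    model, threshold = threshold)
}
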