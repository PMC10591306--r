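---
title: "Methods: plans, the CURB65 application, and the synthetic feed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plans, the CURB65 application, and the synthetic feed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardflow)
```

This vignette is the package's own account of its design: the execution
model and its assumptions, the parameters that matter, what the synthetic
feed does and does not emulate, and the choices made where the design was
genuinely open.

## The execution model

A **plan** is a directed graph of named **steps** with a designated start
step and at least one terminal step. Each step combines:

* a **data input** — a (possibly collated) data source whose schema
  declares the fields, kinds, units, defaults and permitted ranges of the
  values the step consumes. Records are validated and coerced before use;
  a record that cannot satisfy the schema never reaches an algorithm.
* an **algorithm** — one of three modalities: a *score algorithm*
  (weighted sum of boolean risk-factor predicates), a *logical algorithm*
  (ordered if/then rules with a default label), or a *predictive
  algorithm* (a serialized binary classifier behind an encoder).
* a **decision** — a selector mapping the algorithm result to exactly one
  option label, each label naming the successor step.
* **actions** — state writes fired at one of four trigger points
  (`on_data`, `on_result`, `on_decision_made`, `on_decision_actioned`).
  Writes triggered `on_decision_made` are persisted before the journey
  advances; this ordering is asserted by the test suite.

`check_plan()` validates structure before execution: unknown or dangling
step references, steps unreachable from the start, steps from which no
terminal step can be reached, selectors that cannot cover their
algorithm's output range, and writes to undeclared states. Reachability
treats the *discharge transition as an implicit edge* from every
non-terminal step to the plan's `on_discharge` terminal — this is a
deliberate semantic choice: the hourly re-assessment cycle of the CAP
plan is an intentional loop whose only exit is discharge, and the engine
can finalise any live journey there, so plans with assessment cycles are
valid without artificial escape edges.

### Time, availability, and the two execution modes

The clock advances in fixed increments (default one hour). An
observation is *available* at time `t` if it is the most recent value for
its field with a timestamp at or before `t` and no older than the
look-back window (default 24 h — a deliberately generous staleness bound
for a setting where vitals are charted a few times per shift; it is an
engine option). Demographics are constant over the admission. Ties at
identical timestamps resolve to the last-arrived value, matching the
last-source-wins precedence of collated sources.

Within one tick a journey advances through steps until it reaches a
terminal step, runs out of required data (it **pauses**; it retries at
the next tick, so new data resumes it), or would re-enter a step it
already ran this tick — the hold point that turns the CAP plan's
assessment loop into one evaluation per hour. An algorithm failure marks
only that journey errored; other journeys are unaffected. At discharge
the journey finalises at the `on_discharge` terminal; a journey still
paused at that moment finalises with an `incomplete` marker rather than
erroring.

**Replay mode** pre-loads a static store and ticks every journey from
admission to discharge. **Live mode** delivers messages in timestamp
order and lets each journey's clock catch up behind the delivered
horizon. A tick at time `t` only runs once the horizon has moved *past*
`t`, so every message stamped at or before `t` is already in the feed —
this strict inequality is what makes the two modes produce byte-identical
journey logs for the same data, a property the acceptance suite asserts.

### Missing data

Schema fields may declare defaults, substituted when the field is absent
(a field cannot be both required and defaulted). Required fields with no
value pause the journey rather than erroring — in a ward setting "the
blood result is not back yet" is the normal case, not an exception.
There is no imputation: a paused assessment simply contributes no
severity reading for that hour.

## The CURB65 application

The score awards one point each for confusion, urea > 7 mmol/L,
respiratory rate ≥ 30/min, low blood pressure (systolic < 90 mmHg *or*
diastolic ≤ 60 mmHg), and age ≥ 65 years; bands are Low (0–1),
Moderate (2), High (3–5). The band thresholds are fixed; the numeric
factor cut-offs come from the standard clinical definition and are
config-overridable (`curb65_algorithm(cutoffs = ...)`) for local
guideline variants. Confusion is consumed as a pre-recorded boolean
vital; no cognitive-test score is computed. The blood-pressure factor
uses strict `<` for systolic and `≤` for diastolic, and urea uses strict
`>` — boundary behaviour is pinned by enumeration tests against an
independent per-predicate oracle.

CAP identification is membership of the primary-position ICD-10 code's
three-character category in J12–J18. The code set is an argument
everywhere it is used; the choice of primary position only is
deliberate (secondary pneumonia codes usually mark hospital-acquired or
aspiration events in this coding style).

## Predictive algorithms, metadata and explanations

A predictive algorithm wraps an opaque classifier behind a schema and an
encoder (declared fields, in model input order, booleans as 0/1). The
probability threshold defaults to 0.5 with `≥` at the boundary mapping to
the positive class — the boundary direction is arbitrary but documented
and tested. Performance metadata (AUC via ROC, plus sensitivity,
specificity, accuracy and positive predictive value at the threshold) is
computed once and cached with the algorithm, so dashboards render without
touching the model; "predictive power" in the model panel is implemented
as positive predictive value. Artefacts serialize to a single JSON
document (schema, parameters, cached metadata, base64 model blob, format
version) with numbers at 17 significant digits so cached metrics survive
the round trip exactly; loading verifies the format version and,
optionally, the schema version of the caller's data by exact string
match.

Local explanations use a perturbation-fitted linear surrogate: `n`
perturbed copies of the encoded record (Gaussian noise at one training
standard deviation per numeric feature; boolean features flipped with
probability 0.25), weighted by an exponential kernel
`exp(-d²/w²)` on the standardized distance with width
`w = 0.75·sqrt(n_features)`, and a weighted ridge fit (penalty 0.01,
intercept unpenalized) of the model probabilities on the standardized
offsets. A feature's contribution is its surrogate coefficient — the
local effect of a one-scale-unit change — so contributions are stable
under unit changes that are reflected in the stored feature scales. The
explainer is seed-deterministic; tests cover recovery of known monotone
dependence, near-zero attribution for constant models, and coefficient
recovery for linear models. The ridge penalty biases coefficients
slightly toward zero; at the default 500 perturbations this bias is
negligible relative to sampling noise.

The mortality model shipped in examples is a *demonstration*: a
gradient-boosted tree classifier trained on synthetic cohorts, with
features (age; worst urea, CRP and respiratory rate; lowest systolic
pressure; any confusion) chosen from the simulated schema because they
are the severity-relevant aggregates the feed produces. It stands for
the class of embedded models, not for any deployed hospital model.

## The synthetic admissions feed

The feed emulates the *record and field structure* and message timing of
a hospital data warehouse: admission messages with demographics and ICD
codes, timestamped vital and lab panels, an imaging-report stub for CAP
admissions, discharge and outcome messages, all as newline-delimited
JSON. Defaults are the package's declared study conditions: 50% CAP
prevalence (deliberately enriched far above the ~1% of a general
admission stream, since the pipeline's subject is the CAP pathway);
severity mix Low 0.45 / Moderate 0.25 / High 0.30; log-normal length of
stay with median 72 h clipped to 12–240 h; two extra observation panels
per day; 45% of CAP admissions reviewed; 30% reviewer mis-banding; 20%
of reviews without a usable score. Mortality is sampled with a logistic
link increasing in severity band and age — purely illustrative labels
for the demonstration classifier.

Severity ground truth is enforced **constructively**, not by rejection: a
target band fixes a factor count (Low draws 0–1, Moderate exactly 2,
High 3–5), a factor subset of that size is drawn (age determines the age
factor, so age is drawn consistently), and observation panels are safe
for non-chosen factors everywhere, safe for chosen factors before a
sampled peak hour and triggering from the peak onwards, with full panels
emitted at admission and at the peak hour. Safe and triggering draws sit
clear of the cut-offs so carried-forward values can never flip a factor.
Consequently the hourly CURB65 maximum over the stay equals the target
band *exactly*, and engine replay must recover it for 100% of CAP
admissions — the generator–scorer closed loop that anchors the test
suite.

What the feed does **not** emulate: physiological time-series structure
beyond threshold crossing (no drift, no autocorrelation), free-text
reports beyond a flagged stub, coding noise, transfers, or re-admission
of the same patient. Passing the closed loop therefore demonstrates that
the engine computes the severity pathway correctly over arbitrary timed
data — it says nothing about CURB65's clinical validity or about
real-data missingness patterns, which are far messier than the feed's.

Simulated reviews perturb the true band one level with probability
`reviewer_error`: Moderate and High move down, emulating the manual
under-scoring observed when reviews happen before deterioration or on
incomplete data; Low moves *up* to Moderate, its only available
neighbour. The upward direction for Low is a deliberate deviation from a
strictly-downward error model: with a strictly downward rule, errors on
Low-band admissions would be unobservable and the realized disagreement
rate would under-shoot the configured error rate, breaking the pipeline's
error-recovery property. With every error event changing the band, the
evaluation's disagreement fraction is an unbiased estimate of
`reviewer_error`, which the acceptance suite checks at three binomial
standard errors with 1,000 reviewed admissions.

## The evaluation pipeline

`evaluate_severity()` mirrors a retrospective quality-improvement
comparison: identify CAP admissions, replay the plan hourly, take each
journey's maximum severity band, link manual reviews (equal patient ID,
review admission datetime within the admission interval ± 24 h; matching
is one-to-one with earliest-review-wins, and a review eligible for
several admissions is kept by the first with a logged warning), and
cross-tabulate the reviewer's single manual band against the engine's
hourly maximum. The comparison is intentionally *not* time-aligned to
the review instant: a reviewer scores once, the engine scores hourly, and
the divergence between a snapshot and a maximum is part of what the
comparison is designed to surface, not a bug. Reviews without a usable
score are reported as the with/without-score split rather than dropped
silently. Arithmetic consistency (reviewed + unreviewed = CAP total;
cross-tab marginals = compared pairs) is asserted on every run.

## Numerical and interface choices

* Collated sources merge with last-source-wins on field collisions; the
  order is the declared constituent order, so precedence is deterministic
  and testable by order-swap.
* Datetimes are stored timezone-naive in local hospital time; replay
  needs only ordering, and all formats use `%Y-%m-%d %H:%M:%S`.
* Schema versions compare by exact string match; a mismatch between a
  serialized algorithm and supplied data is an error, not a warning.
* Plans can be declared in one YAML document (`read_plan()`); transforms
  are referenced by name from a built-in registry because arbitrary code
  in config files would make plan documents unauditable.
* The broker is an in-memory or file-backed (NDJSON) queue abstraction;
  no external message transport is required. Stores are delimited text,
  SQLite, or folded from message streams.
* Problem sizes in the test and acceptance suites (1,000-admission
  cohorts for the closed-loop and reviewer-recovery checks, 60 for mode
  equivalence, 50 for determinism) were chosen as the smallest sizes at
  which the stochastic tolerances are meaningful for the binomial checks
  while keeping the suites quick to run.

## Known limitations

* No HL7/FHIR parsing; inputs are delimited text, SQLite, or JSON
  messages in the package's own shapes.
* No authentication, distributed execution, HTTP API, or dashboard; the
  renderers emit documents (Mermaid text, HTML) for embedding elsewhere.
* The pause policy has no timeout except discharge finalisation; in a
  true live deployment one would add a maximum-pause alert.
* The demonstration mortality model and all simulator distributions are
  declared fixtures — none are fitted to real hospital data.
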