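# Plan execution. An engine holds a checked plan, a per-admission data
# feed, and one journey per admission. Time moves in fixed increments
# (hourly by default) per journey; a value is "available" at time t if it
# is the most recent observation with timestamp <= t inside the look-back
# window. Within one tick a journey advances through steps until it hits a
# terminal step, runs out of data (pause), or would re-enter a step it has
# already run this tick (the hold point of looping plans, e.g. the hourly
# severity re-assessment cycle).

DEMOGRAPHIC_FIELDS <- c("admission_id", "patient_id", "age", "sex",
                        "primary_icd", "icd_codes")

#' Create an execution engine
#'
#' The engine executes a structurally valid plan over admission data,
#' either pre-loaded from a store ([run_replay()]) or delivered
#' incrementally as messages ([run_live()] / [handle_message()]).
#'
#' @param plan A [plan()]; [check_plan()] must report no faults.
#' @param lookback_hours Observation staleness window: a value is usable at
#'   time t if recorded within this many hours before t.
#' @param step_hours Clock increment per tick.
#' @param max_hours Safety horizon for admissions with no recorded
#'   discharge: their journeys finalise this many hours after admission.
#' @param on_unknown_admission `"queue"` (hold data until the admission
#'   message arrives) or `"reject"` (drop with a warning).
#' @param outbox A broker queue ([in_memory_queue()] or [file_queue()])
#'   receiving engine outcome records.
#' @return A `wf_engine` (mutable environment).
#' @export
new_engine <- function(plan, lookback_hours = 24, step_hours = 1,
                       max_hours = 24 * 45,
                       on_unknown_admission = c("queue", "reject"),
                       outbox = in_memory_queue()) {
  faults <- check_plan(plan)
  if (nrow(faults))
    wf_abort("wf_config_error",
             sprintf("plan '%s' fails structural checks: %s", plan$name,
                     paste(faults$type, faults$subject, collapse = "; ")))
  e <- new.env(parent = emptyenv())
  e$plan <- plan
  e$lookback <- lookback_hours * 3600
  e$step <- step_hours * 3600
  e$max_span <- max_hours * 3600
  e$now <- -Inf
  e$feeds <- new.env(parent = emptyenv())
  e$journeys <- new.env(parent = emptyenv())
  e$pending <- new.env(parent = emptyenv())
  e$unknown <- match.arg(on_unknown_admission)
  e$outbox <- outbox
  class(e) <- "wf_engine"
  e
}

#' @export
print.wf_engine <- function(x, ...) {
  js <- ls(x$journeys)
  st <- vapply(js, function(id) x$journeys[[id]]$status, character(1))
  cat(sprintf("<wf_engine> plan '%s': %d journeys (%s)\n", x$plan$name,
              length(js),
              if (length(js)) paste(names(table(st)), table(st),
                                    collapse = ", ") else "none"))
  invisible(x)
}

new_feed <- function(admission_id, admitted, demog) {
  f <- new.env(parent = emptyenv())
  f$admission_id <- admission_id
  f$admitted <- as.numeric(admitted)
  f$discharged <- NA_real_
  f$demog <- demog
  f$obs <- new.env(parent = emptyenv())
  f
}

feed_append <- function(feed, field, value, ts) {
  o <- feed$obs[[field]]
  if (is.null(o)) o <- list(times = numeric(0), values = list())
  o$times <- c(o$times, as.numeric(ts))
  o$values <- c(o$values, list(value))
  feed$obs[[field]] <- o
  invisible(feed)
}

# Most recent value for `field` at time t within the look-back window;
# demographics are constant over the admission. NULL when unavailable.
# Ties at identical timestamps resolve to the last-arrived value.
feed_value_at <- function(feed, field, t, lookback) {
  d <- feed$demog[[field]]
  if (!is.null(d)) return(d)
  o <- feed$obs[[field]]
  if (is.null(o)) return(NULL)
  times <- o$times
  if (is.unsorted(times)) {
    ord <- order(times)        # stable: equal stamps keep arrival order
    times <- times[ord]
    o <- list(times = times, values = o$values[ord])
    feed$obs[[field]] <- o
  }
  i <- findInterval(t, times)
  if (i == 0L || times[i] < t - lookback) return(NULL)
  o$values[[i]]
}

new_journey <- function(admission_id, start_step, t0) {
  j <- new.env(parent = emptyenv())
  j$admission_id <- admission_id
  j$status <- "active"
  j$incomplete <- FALSE
  j$current_step <- start_step
  j$next_time <- as.numeric(t0)
  j$v_step <- character(0)
  j$v_time <- numeric(0)
  j$v_value <- character(0)
  j$v_label <- character(0)
  j$states <- new.env(parent = emptyenv())
  j
}

record_visit <- function(j, step_name, t, result, label) {
  j$v_step <- c(j$v_step, step_name)
  j$v_time <- c(j$v_time, t)
  v <- if (is.null(result) || is.null(result$value)) NA_character_
       else as.character(result$value)
  j$v_value <- c(j$v_value, v)
  j$v_label <- c(j$v_label, label %||% NA_character_)
}

state_write <- function(j, state, value, t) {
  s <- j$states[[state]]
  if (is.null(s)) s <- list(times = numeric(0), values = list())
  s$times <- c(s$times, t)
  s$values <- c(s$values, list(value))
  j$states[[state]] <- s
}

fire_actions <- function(st, trigger, j, result, decision_label, t) {
  for (a in st$actions) {
    if (a$trigger != trigger) next
    state_write(j, a$state, action_payload(a, result, decision_label), t)
  }
}

gather_input <- function(engine, feed, source, t) {
  leaves <- leaf_sources(source)
  records <- stats::setNames(vector("list", length(leaves)),
                             vapply(leaves, `[[`, character(1), "name"))
  for (s in leaves) {
    rec <- list()
    for (f in schema_field_names(s$schema)) {
      v <- feed_value_at(feed, f, t, engine$lookback)
      if (!is.null(v)) rec[[f]] <- v
    }
    records[[s$name]] <- rec
  }
  collate_source(source, records)
}

effective_discharge <- function(engine, feed) {
  if (!is.na(feed$discharged)) feed$discharged
  else feed$admitted + engine$max_span
}

complete_journey <- function(engine, j, step_name, t, incomplete = FALSE) {
  record_visit(j, step_name, t, NULL, NA_character_)
  j$current_step <- step_name
  j$status <- "complete"
  if (incomplete) j$incomplete <- TRUE
  sev <- j$states[["severity"]]
  queue_push(engine$outbox, message_event(
    "outcome", j$admission_id, as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
    payload = list(source = "engine", final_step = step_name,
                   incomplete = j$incomplete,
                   max_severity = if (!is.null(sev))
                     severity_bands()[max(severity_rank(unlist(sev$values)))]
                   else NULL)))
}

advance_journey <- function(engine, j, t) {
  feed <- engine$feeds[[j$admission_id]]
  disch <- effective_discharge(engine, feed)
  if (t >= disch) {
    # finalise: route to the discharge terminal; a journey still waiting on
    # data finalises with an incomplete marker rather than erroring
    target <- engine$plan$on_discharge %||% j$current_step
    st <- engine$plan$steps[[j$current_step]]
    was_paused <- identical(j$status, "paused")
    if (!st$terminal)
      complete_journey(engine, j, target, disch, incomplete = was_paused)
    else j$status <- "complete"
    return(invisible())
  }
  ran <- character(0)
  repeat {
    st <- engine$plan$steps[[j$current_step]]
    if (st$terminal) {
      complete_journey(engine, j, st$name, t)
      break
    }
    if (st$name %in% ran) break   # hold until the next tick
    ran <- c(ran, st$name)
    result <- NULL
    if (!is.null(st$algorithm)) {
      res <- tryCatch({
        rec <- gather_input(engine, feed, st$input, t)
        fire_actions(st, "on_data", j, NULL, NULL, t)
        run_algorithm(st$algorithm, rec)
      },
      wf_missing_field = function(e) { j$status <- "paused"; e },
      wf_error = function(e) { j$status <- "errored"; e })
      if (is_wf_error(res)) break
      j$status <- "active"
      result <- res
      fire_actions(st, "on_result", j, result, NULL, t)
    }
    if (!is.null(st$decision)) {
      label <- tryCatch(select_option(st$decision, result),
                        wf_error = function(e) { j$status <- "errored"; e })
      if (is_wf_error(label)) break
      nxt <- unname(st$decision$options[[label]])
    } else {
      label <- NULL
      nxt <- st$next_step
    }
    # on_decision_made state writes persist before the journey advances
    fire_actions(st, "on_decision_made", j, result, label, t)
    record_visit(j, st$name, t, result, label)
    j$current_step <- nxt
    fire_actions(st, "on_decision_actioned", j, result, label, t)
  }
  invisible()
}

#' Advance the engine clock by one increment
#'
#' Every active or paused journey whose next evaluation time has been
#' reached is advanced: its step input is collated from the data available
#' at that time, the algorithm runs, actions fire in trigger order and the
#' decision selects the next step. Journeys lacking required data pause;
#' an algorithm failure marks that journey errored without halting the
#' others.
#'
#' @param engine A `wf_engine`.
#' @return Invisibly, the number of journeys advanced.
#' @export
tick <- function(engine) {
  n <- 0L
  for (id in ls(engine$journeys)) {
    j <- engine$journeys[[id]]
    if (j$status %in% c("complete", "errored")) next
    # strict inequality: a tick at time t only runs once the delivered
    # horizon has moved past t, so every message stamped <= t is in the
    # feed. This is what makes live processing reproduce replay exactly.
    if (j$next_time >= engine$now) next
    t <- j$next_time
    advance_journey(engine, j, t)
    j$next_time <- t + engine$step
    n <- n + 1L
  }
  invisible(n)
}

#' Deliver one message to the engine
#'
#' Admission messages open a new journey at the plan's start step
#' (duplicates are idempotent); lab/vital/imaging payloads are stored
#' against the admission's feed, field by field; discharge messages set the
#' discharge time that finalises the journey; outcome messages are stored
#' for later model training. Data arriving for an unknown admission is
#' queued until its admission message arrives (or rejected, per the engine
#' option). Paused journeys holding for the data resume on the next tick.
#'
#' @param engine A `wf_engine`.
#' @param msg A [message_event()].
#' @return Invisibly, `TRUE` if the message was accepted.
#' @export
handle_message <- function(engine, msg) {
  stopifnot(inherits(msg, "wf_message"))
  ts <- as.numeric(msg$timestamp)
  engine$now <- max(engine$now, ts)
  id <- msg$admission_id
  feed <- engine$feeds[[id]]
  if (msg$kind == "admission") {
    if (!is.null(feed)) return(invisible(TRUE))  # idempotent duplicate
    p <- msg$payload
    demog <- list(admission_id = id,
                  patient_id = p$patient_id %||% NA_character_,
                  age = p$age, sex = p$sex %||% NA_character_,
                  primary_icd = p$primary_icd %||% NA_character_,
                  icd_codes = unlist(p$icd_codes) %||% character(0))
    engine$feeds[[id]] <- new_feed(id, ts, demog)
    engine$journeys[[id]] <- new_journey(id, engine$plan$start, ts)
    held <- engine$pending[[id]]
    if (!is.null(held)) {
      rm(list = id, envir = engine$pending)
      for (m in held) handle_message(engine, m)
    }
    return(invisible(TRUE))
  }
  if (is.null(feed)) {
    if (engine$unknown == "queue") {
      engine$pending[[id]] <- c(engine$pending[[id]] %||% list(), list(msg))
      return(invisible(TRUE))
    }
    warning(sprintf("message for unknown admission '%s' rejected", id))
    return(invisible(FALSE))
  }
  if (msg$kind == "discharge") {
    feed$discharged <- ts
  } else if (msg$kind %in% c("lab", "vital", "imaging_report")) {
    for (f in names(msg$payload)) feed_append(feed, f, msg$payload[[f]], ts)
  } else if (msg$kind == "outcome") {
    feed$outcome <- msg$payload
  }
  invisible(TRUE)
}

engine_done <- function(engine) {
  for (id in ls(engine$journeys)) {
    if (engine$journeys[[id]]$status %in% c("active", "paused")) return(FALSE)
  }
  TRUE
}

drain_engine <- function(engine) {
  engine$now <- Inf
  while (!engine_done(engine)) {
    if (tick(engine) == 0L) break
  }
  invisible(engine)
}

snapshot_journey <- function(j) {
  states <- lapply(stats::setNames(ls(j$states), ls(j$states)), function(nm) {
    s <- j$states[[nm]]
    data.frame(time = as.POSIXct(s$times, origin = "1970-01-01", tz = "UTC"),
               value = vapply(s$values, function(v) as.character(v),
                              character(1)),
               stringsAsFactors = FALSE)
  })
  structure(list(admission_id = j$admission_id, status = j$status,
                 incomplete = j$incomplete,
                 visits = data.frame(
                   step = j$v_step,
                   time = as.POSIXct(j$v_time, origin = "1970-01-01",
                                     tz = "UTC"),
                   value = j$v_value, label = j$v_label,
                   stringsAsFactors = FALSE),
                 states = states),
            class = "wf_journey")
}

#' @export
print.wf_journey <- function(x, ...) {
  cat(sprintf("<wf_journey> %s [%s%s]: %d visits\n", x$admission_id,
              x$status, if (x$incomplete) ", incomplete" else "",
              nrow(x$visits)))
  invisible(x)
}

engine_result <- function(engine) {
  ids <- ls(engine$journeys)
  journeys <- lapply(stats::setNames(ids, ids), function(id)
    snapshot_journey(engine$journeys[[id]]))
  logs <- do.call(rbind, lapply(journeys, function(jn) {
    if (nrow(jn$visits) == 0L) return(NULL)
    cbind(data.frame(admission_id = jn$admission_id,
                     stringsAsFactors = FALSE), jn$visits)
  }))
  if (is.null(logs))
    logs <- data.frame(admission_id = character(), step = character(),
                       time = as.POSIXct(character(), tz = "UTC"),
                       value = character(), label = character())
  rownames(logs) <- NULL
  structure(list(journeys = journeys, log = logs,
                 outbox = queue_drain(engine$outbox)),
            class = "wf_run")
}

#' @export
print.wf_run <- function(x, ...) {
  st <- vapply(x$journeys, `[[`, character(1), "status")
  cat(sprintf("<wf_run> %d journeys (%s); %d log rows\n", length(x$journeys),
              paste(names(table(st)), table(st), collapse = ", "),
              nrow(x$log)))
  invisible(x)
}

ingest_store <- function(engine, store) {
  adm <- store$admissions
  for (i in seq_len(nrow(adm))) {
    id <- adm$admission_id[i]
    demog <- list(admission_id = id, patient_id = adm$patient_id[i],
                  age = adm$age[i], sex = adm$sex[i],
                  primary_icd = adm$primary_icd[i],
                  icd_codes = strsplit(adm$icd_codes[i] %||% "", ";")[[1]])
    feed <- new_feed(id, adm$admitted[i], demog)
    if (!is.na(adm$discharged[i])) feed$discharged <- as.numeric(adm$discharged[i])
    engine$feeds[[id]] <- feed
    engine$journeys[[id]] <- new_journey(id, engine$plan$start, adm$admitted[i])
  }
  obs <- store$observations
  if (nrow(obs)) {
    ord <- order(obs$timestamp)
    obs <- obs[ord, , drop = FALSE]
    for (i in seq_len(nrow(obs))) {
      feed <- engine$feeds[[obs$admission_id[i]]]
      if (!is.null(feed))
        feed_append(feed, obs$field[i], obs$value[i], obs$timestamp[i])
    }
  }
  invisible(engine)
}

#' Execute a plan over a static store (hourly replay)
#'
#' Equivalent to ticking the clock hourly from each admission's start to
#' its discharge with all stored data pre-loaded but filtered by
#' availability time. Deterministic given an identical store.
#'
#' @param plan A checked [plan()].
#' @param store A [new_store()] / [as_store()] replay store.
#' @param ... Engine options passed to [new_engine()].
#' @return A `wf_run`: named list of journeys, a journey log data.frame
#'   (one row per transition), and the drained outbox.
#' @export
run_replay <- function(plan, store, ...) {
  engine <- new_engine(plan, ...)
  ingest_store(engine, store)
  drain_engine(engine)
  engine_result(engine)
}

#' Execute a plan over an ordered message stream (near-real-time mode)
#'
#' Messages are delivered in timestamp order; after each delivery the
#' clock catches up, advancing every journey whose next evaluation time
#' has been reached. Once the stream ends the engine drains. Replay of a
#' store and live processing of the same data re-emitted as ordered
#' messages produce identical journey logs.
#'
#' @param plan A checked [plan()].
#' @param messages A message data.frame (see [simulate_cohort()],
#'   [read_messages()]).
#' @param ... Engine options passed to [new_engine()].
#' @return A `wf_run`, as [run_replay()].
#' @export
run_live <- function(plan, messages, ...) {
  engine <- new_engine(plan, ...)
  ord <- order(messages$timestamp)
  messages <- messages[ord, , drop = FALSE]
  for (i in seq_len(nrow(messages))) {
    handle_message(engine, message_event(
      messages$kind[i], messages$admission_id[i], messages$timestamp[i],
      messages$payload[[i]]))
    while (tick(engine) > 0L) {}
  }
  drain_engine(engine)
  engine_result(engine)
}
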