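#' Decisions: route an algorithm result to the next step
#'
#' A decision holds a non-empty map from option label to next-step name and
#' a selector turning an [algorithm_result()] into exactly one option
#' label. Built-in selectors cover the common cases and declare their
#' domain, which lets [check_plan()] verify the selector is total over the
#' algorithm's output range:
#'
#' * `selector_band(cutoffs)` — maps an integer score through
#'   [stratify_severity()] (or custom score-to-band cutoffs) to a band
#'   label;
#' * `selector_label()` — uses the result's own label (logical and
#'   predictive algorithms);
#' * `selector_constant(label)` — always the same option (pass-through
#'   steps).
#'
#' @param options Named character vector: option label -> next step name.
#' @param selector A selector object, or `function(result) label`.
#' @return A `wf_decision`.
#' @export
decision <- function(options, selector = selector_label()) {
  if (length(options) == 0L || is.null(names(options)) ||
      any(!nzchar(names(options))))
    wf_abort("wf_config_error", "options must be a named character vector")
  if (anyDuplicated(names(options)))
    wf_abort("wf_config_error", "option labels must be unique")
  if (is.function(selector))
    selector <- structure(list(type = "custom", fn = selector),
                          class = "wf_selector")
  structure(list(options = options, selector = selector),
            class = "wf_decision")
}

#' @rdname decision
#' @export
selector_label <- function()
  structure(list(type = "label"), class = "wf_selector")

#' @rdname decision
#' @export
selector_band <- function()
  structure(list(type = "band"), class = "wf_selector")

#' @param label Constant option label.
#' @rdname decision
#' @export
selector_constant <- function(label)
  structure(list(type = "constant", label = label), class = "wf_selector")

select_option <- function(dec, result) {
  label <- switch(dec$selector$type,
                  label = result$label %||% as.character(result$value),
                  band = stratify_severity(result$value),
                  constant = dec$selector$label,
                  custom = dec$selector$fn(result))
  if (is.null(label) || !label %in% names(dec$options))
    abort_invalid_value("decision", sprintf(
      "selector produced '%s', not one of {%s}",
      label %||% "<NULL>", paste(names(dec$options), collapse = ", ")))
  label
}

# Labels a selector can emit, or NULL when not statically known. Used by
# check_plan for totality checking.
selector_codomain <- function(selector, algorithm = NULL) {
  switch(selector$type,
         band = severity_bands(),
         constant = selector$label,
         label = if (inherits(algorithm, "wf_logical_algorithm"))
           algorithm$labels
         else if (inherits(algorithm, "wf_predictive_algorithm"))
           unname(algorithm$classes),
         NULL)
}

#' Event-driven step actions
#'
#' Actions fire at defined points while a step runs: `on_data` (validated
#' input available), `on_result` (algorithm has run), `on_decision_made`
#' (option selected, before the journey advances) and
#' `on_decision_actioned` (after the journey has advanced). The stock
#' effect writes a state value: `from` is one of `"value"`, `"label"`,
#' `"decision"`, or `list(constant = x)`. State writes triggered
#' `on_decision_made` are persisted before the journey moves on.
#'
#' @param trigger One of the four trigger points.
#' @param state Name of the plan state variable to write.
#' @param from What to write: `"value"`, `"label"`, `"decision"` or
#'   `list(constant = x)`.
#' @return A `wf_action`.
#' @export
action_set_state <- function(trigger, state, from = "value") {
  triggers <- c("on_data", "on_result", "on_decision_made",
                "on_decision_actioned")
  if (!trigger %in% triggers)
    wf_abort("wf_config_error", sprintf("unknown trigger '%s'", trigger))
  structure(list(trigger = trigger, state = state, from = from),
            class = "wf_action")
}

action_payload <- function(action, result, decision_label) {
  if (is.list(action$from)) return(action$from$constant)
  switch(action$from,
         value = result$value,
         label = result$label %||% result$value,
         decision = decision_label)
}

#' Plan steps
#'
#' The determinative unit of a plan: a data input, an algorithm, a decision
#' routing the result to a successor, and event-driven actions. Terminal
#' steps carry no decision and end the journey. A step may omit the
#' algorithm and decision and instead name a single `next_step`
#' (pass-through steps used to mark journey states).
#'
#' @param name Step identifier.
#' @param input Optional [data_source()] feeding the algorithm.
#' @param algorithm Optional algorithm run on the collated input.
#' @param decision Optional [decision()].
#' @param actions List of [action_set_state()] actions.
#' @param terminal Whether the step ends the journey.
#' @param next_step Single successor for decision-less pass-through steps.
#' @return A `wf_step`.
#' @export
step <- function(name, input = NULL, algorithm = NULL, decision = NULL,
                 actions = list(), terminal = FALSE, next_step = NULL) {
  if (terminal && (!is.null(decision) || !is.null(next_step)))
    wf_abort("wf_config_error",
             sprintf("terminal step '%s' cannot have successors", name))
  if (!terminal && is.null(decision) && is.null(next_step))
    wf_abort("wf_config_error",
             sprintf("non-terminal step '%s' needs a decision or next_step",
                     name))
  if (!is.null(algorithm) && is.null(input))
    wf_abort("wf_config_error",
             sprintf("step '%s' has an algorithm but no input source", name))
  structure(list(name = name, input = input, algorithm = algorithm,
                 decision = decision, actions = actions, terminal = terminal,
                 next_step = next_step),
            class = "wf_step")
}

step_successors <- function(s) {
  if (s$terminal) character(0)
  else if (!is.null(s$decision)) unname(s$decision$options)
  else s$next_step
}

# Successors for graph analysis: every non-terminal step also carries the
# implicit discharge transition, since the engine can finalise any live
# journey at the plan's on_discharge terminal.
step_successors_graph <- function(s, plan) {
  succ <- step_successors(s)
  if (!s$terminal && !is.null(plan$on_discharge))
    succ <- union(succ, plan$on_discharge)
  succ
}

#' Plans: directed graphs of steps
#'
#' A plan is the declarative container of a decision-support workflow: a
#' map of named steps, a start step, the declared state-variable names, and
#' the name of the terminal step a journey is routed to when its admission
#' is discharged. Construct with `plan()`, then verify structure with
#' [check_plan()] before execution.
#'
#' @param name Plan identifier.
#' @param steps List of [step()] objects.
#' @param start Name of the start step.
#' @param states Character vector of declared state-variable names.
#' @param on_discharge Name of the terminal step journeys finalise at when
#'   the admission is discharged.
#' @return A `wf_plan`.
#' @export
plan <- function(name, steps, start, states = character(),
                 on_discharge = NULL) {
  nms <- vapply(steps, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    wf_abort("wf_config_error", "step names must be unique")
  names(steps) <- nms
  structure(list(name = name, steps = steps, start = start, states = states,
                 on_discharge = on_discharge),
            class = "wf_plan")
}

#' @export
print.wf_plan <- function(x, ...) {
  cat(sprintf("<wf_plan> %s: %d steps, start '%s'\n", x$name,
              length(x$steps), x$start))
  for (s in x$steps) {
    succ <- step_successors(s)
    cat(sprintf("  %s%s%s\n", s$name,
                if (s$terminal) " [terminal]" else "",
                if (length(succ)) paste0(" -> ", paste(succ, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Structural validation of a plan
#'
#' Returns a data.frame of faults (zero rows when the plan is valid) rather
#' than raising: dangling decision targets, steps unreachable from the
#' start, steps from which no terminal step can be reached (dead ends),
#' missing/unknown start step, selectors that are not total over their
#' algorithm's output range, and actions writing undeclared states.
#'
#' @param plan A [plan()].
#' @return data.frame with columns `type`, `subject`, `detail`.
#' @export
check_plan <- function(plan) {
  faults <- list()
  add <- function(type, subject, detail = "")
    faults[[length(faults) + 1L]] <<- data.frame(
      type = type, subject = subject, detail = detail,
      stringsAsFactors = FALSE)

  nms <- names(plan$steps)
  if (!plan$start %in% nms)
    add("MissingStart", plan$start, "start step is not defined")
  if (!is.null(plan$on_discharge) && !plan$on_discharge %in% nms)
    add("DanglingTarget", plan$on_discharge, "on_discharge step not defined")

  for (s in plan$steps) {
    for (t in step_successors(s))
      if (!t %in% nms) add("DanglingTarget", t,
                           sprintf("named by step '%s'", s$name))
    # selector totality, where the codomain is statically known
    if (!is.null(s$decision)) {
      cod <- selector_codomain(s$decision$selector, s$algorithm)
      if (!is.null(cod)) {
        missing_opts <- setdiff(cod, names(s$decision$options))
        if (length(missing_opts))
          add("PartialSelector", s$name,
              sprintf("no option for label(s): %s",
                      paste(missing_opts, collapse = ", ")))
      }
    }
    for (a in s$actions)
      if (!a$state %in% plan$states)
        add("UndeclaredState", a$state, sprintf("written by step '%s'", s$name))
  }

  # reachability from start (BFS over declared successors)
  if (plan$start %in% nms) {
    reach <- bfs_from(plan, plan$start)
    for (nm in setdiff(nms, reach)) add("Unreachable", nm)
    # every step must be able to reach a terminal step
    terminals <- nms[vapply(plan$steps, `[[`, logical(1), "terminal")]
    if (length(terminals) == 0L) {
      add("NoTerminal", plan$name, "plan has no terminal step")
    } else {
      can_end <- reverse_reach(plan, terminals)
      for (nm in setdiff(reach, can_end))
        add("DeadEnd", nm, "no terminal step reachable")
    }
  }

  if (length(faults) == 0L)
    data.frame(type = character(), subject = character(),
               detail = character(), stringsAsFactors = FALSE)
  else do.call(rbind, faults)
}

bfs_from <- function(plan, start) {
  seen <- character(0)
  queue <- start
  while (length(queue)) {
    nm <- queue[[1]]; queue <- queue[-1]
    if (nm %in% seen || !nm %in% names(plan$steps)) next
    seen <- c(seen, nm)
    queue <- c(queue, setdiff(step_successors_graph(plan$steps[[nm]], plan),
                              seen))
  }
  seen
}

# set of steps from which any of `targets` is reachable
reverse_reach <- function(plan, targets) {
  preds <- list()
  for (s in plan$steps)
    for (t in step_successors_graph(s, plan))
      preds[[t]] <- c(preds[[t]], s$name)
  seen <- character(0)
  queue <- targets
  while (length(queue)) {
    nm <- queue[[1]]; queue <- queue[-1]
    if (nm %in% seen) next
    seen <- c(seen, nm)
    queue <- c(queue, setdiff(preds[[nm]] %||% character(0), seen))
  }
  seen
}
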