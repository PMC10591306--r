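# Rendered decision-support artefacts. All renderers are pure functions of
# their inputs: the same journey/result/metadata yields byte-identical
# output, so documents can be cached and re-served without recomputation.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a journey as a flowchart (Mermaid dialect)
#'
#' Produces flowchart markup with the plan's steps as nodes, decision
#' options as labelled edges, and the journey's visited steps highlighted
#' via a `visited` class. With `direct_route_only` the diagram is
#' restricted to the steps actually visited (plus the journey's current
#' step); `show_sources` adds each step's data-source name to its node
#' label.
#'
#' @param journey A `wf_journey`.
#' @param plan The plan the journey ran under.
#' @param direct_route_only Drop unvisited branches.
#' @param show_sources Annotate nodes with their input source names.
#' @return A single string of Mermaid `flowchart TD` markup.
#' @export
render_journey <- function(journey, plan, direct_route_only = FALSE,
                           show_sources = FALSE) {
  stopifnot(inherits(journey, "wf_journey"), inherits(plan, "wf_plan"))
  visited <- unique(journey$visits$step)
  unknown <- setdiff(visited, names(plan$steps))
  if (length(unknown))
    wf_abort("wf_inconsistent_journey",
             sprintf("journey visits step(s) not in plan '%s': %s",
                     plan$name, paste(unknown, collapse = ", ")))
  show <- if (direct_route_only) union(visited, character(0))
          else names(plan$steps)
  if (length(show) == 0L) show <- plan$start

  node_id <- function(nm) gsub("[^A-Za-z0-9_]", "_", nm)
  lines <- c("flowchart TD")
  for (nm in show) {
    st <- plan$steps[[nm]]
    lab <- nm
    if (show_sources && !is.null(st$input))
      lab <- sprintf("%s<br/>[%s]", lab, st$input$name)
    shape <- if (st$terminal) sprintf("%s([\"%s\"])", node_id(nm), lab)
             else sprintf("%s[\"%s\"]", node_id(nm), lab)
    lines <- c(lines, paste0("    ", shape))
  }
  for (nm in show) {
    st <- plan$steps[[nm]]
    if (!is.null(st$decision)) {
      for (opt in names(st$decision$options)) {
        tgt <- st$decision$options[[opt]]
        if (!tgt %in% show) next
        lines <- c(lines, sprintf("    %s -->|%s| %s", node_id(nm), opt,
                                  node_id(tgt)))
      }
    } else if (!is.null(st$next_step) && st$next_step %in% show) {
      lines <- c(lines, sprintf("    %s --> %s", node_id(nm),
                                node_id(st$next_step)))
    }
  }
  lines <- c(lines, "    classDef visited fill:#cde6f7,stroke:#1d6fa5,stroke-width:2px;")
  if (length(visited))
    lines <- c(lines, sprintf("    class %s visited;",
                              paste(vapply(visited, node_id, character(1)),
                                    collapse = ",")))
  paste(lines, collapse = "\n")
}

#' Render a risk-score factor breakdown
#'
#' An HTML table listing each risk factor, whether it was satisfied, and
#' the points awarded, with a total row. The listed points always sum to
#' the result value.
#'
#' @param result An [algorithm_result()] from a score algorithm.
#' @return HTML document text.
#' @export
render_factor_breakdown <- function(result) {
  b <- result$breakdown
  if (is.null(b) || !all(c("factor", "satisfied", "points") %in% names(b)))
    wf_abort("wf_no_breakdown",
             "result carries no per-factor breakdown to render")
  stopifnot(sum(b$points) == result$value)
  rows <- vapply(seq_len(nrow(b)), function(i) sprintf(
    "<tr class=\"%s\"><td>%s</td><td>%s</td><td>%d</td></tr>",
    if (b$satisfied[i]) "satisfied" else "unsatisfied",
    html_escape(b$factor[i]), if (b$satisfied[i]) "yes" else "no",
    b$points[i]), character(1))
  paste0(
    "<table class=\"factor-breakdown\">\n",
    "<tr><th>Risk factor</th><th>Satisfied</th><th>Points</th></tr>\n",
    paste(rows, collapse = "\n"), "\n",
    sprintf("<tr class=\"total\"><td>Total</td><td></td><td>%d</td></tr>\n",
            as.integer(result$value)),
    "</table>")
}

#' Render a prediction with its local explanation
#'
#' An HTML document with the two class probabilities (bar widths in
#' percent; the probabilities sum to 1) and the signed per-feature
#' contributions of the local explanation, ordered by absolute magnitude.
#'
#' @param result An [algorithm_result()] from a predictive algorithm.
#' @param explanation A `wf_explanation` from [explain_local()].
#' @return HTML document text.
#' @export
render_prediction <- function(result, explanation = NULL) {
  probs <- result$context$probabilities
  if (is.null(probs)) probs <- stats::setNames(
    c(1 - result$value, result$value), c("negative", "positive"))
  bars <- vapply(seq_along(probs), function(i) sprintf(
    "<div class=\"prob\"><span>%s</span><div class=\"bar\" style=\"width:%.1f%%\"></div><span>%.3f</span></div>",
    html_escape(names(probs)[i]), 100 * probs[i], probs[i]), character(1))
  out <- paste0("<div class=\"prediction\">\n",
                sprintf("<p>Predicted: <b>%s</b> (p = %.3f)</p>\n",
                        html_escape(result$label %||% ""), result$value),
                paste(bars, collapse = "\n"), "\n")
  if (!is.null(explanation)) {
    ord <- order(abs(explanation$contribution), decreasing = TRUE)
    ex <- explanation[ord, , drop = FALSE]
    rows <- vapply(seq_len(nrow(ex)), function(i) sprintf(
      "<tr class=\"%s\"><td>%s</td><td>%s</td><td>%+.4f</td></tr>",
      if (ex$contribution[i] >= 0) "pushes-positive" else "pushes-negative",
      html_escape(ex$feature[i]), format(ex$value[i]),
      ex$contribution[i]), character(1))
    out <- paste0(out,
                  "<table class=\"explanation\">\n",
                  "<tr><th>Feature</th><th>Value</th><th>Contribution</th></tr>\n",
                  paste(rows, collapse = "\n"), "\n</table>\n")
  }
  paste0(out, "</div>")
}

#' Render the model performance panel
#'
#' The model-overview document: area under the curve, accuracy, predictive
#' power (positive predictive value), sensitivity and specificity, each
#' formatted to three decimals. Renders from cached metadata alone, with
#' no access to the model.
#'
#' @param metadata A [model_metadata()].
#' @return HTML document text.
#' @export
render_model_panel <- function(metadata) {
  stopifnot(inherits(metadata, "wf_model_metadata"))
  shown <- c("Area under the curve" = "auc",
             "Accuracy" = "accuracy",
             "Predictive power (PPV)" = "positive_predictive_value",
             "Sensitivity" = "sensitivity",
             "Specificity" = "specificity")
  for (key in shown) {
    v <- metadata[[key]]
    if (is.null(v) || is.na(v))
      wf_abort("wf_missing_metric", sprintf("metadata is missing '%s'", key))
  }
  rows <- vapply(names(shown), function(lbl) sprintf(
    "<tr><td>%s</td><td>%.3f</td></tr>", html_escape(lbl),
    metadata[[shown[[lbl]]]]), character(1))
  paste0("<table class=\"model-panel\">\n",
         sprintf("<caption>Model performance (%s)</caption>\n",
                 html_escape(metadata$computed_on)),
         paste(rows, collapse = "\n"), "\n</table>")
}
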