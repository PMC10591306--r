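# Replay stores and message streams.
#
# The engine consumes admission data in one of two shapes:
#   * a message stream: one JSON object per event (admission, lab, vital,
#     imaging_report, discharge, outcome), newline-delimited on disk;
#   * a static replay store: three tables (admissions, observations,
#     outcomes), persisted as delimited text files or a SQLite database.
# `as_store()` folds a stream into a store; both shapes drive the same
# plan, which is what makes the replay/live duality testable.

MESSAGE_KINDS <- c("admission", "discharge", "lab", "vital",
                   "imaging_report", "outcome")

parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                            "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

format_time <- function(t) format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")

#' Build a message
#'
#' @param kind One of `admission`, `discharge`, `lab`, `vital`,
#'   `imaging_report`, `outcome`.
#' @param admission_id Admission identifier the event belongs to.
#' @param timestamp Event time (`POSIXct` or parseable text).
#' @param payload Named list of event fields.
#' @return A `wf_message`.
#' @export
message_event <- function(kind, admission_id, timestamp, payload = list()) {
  if (!kind %in% MESSAGE_KINDS)
    wf_abort("wf_config_error", sprintf("unknown message kind '%s'", kind))
  structure(list(kind = kind, admission_id = admission_id,
                 timestamp = parse_time(timestamp), payload = payload),
            class = "wf_message")
}

messages_df <- function(msgs) {
  data.frame(
    kind = vapply(msgs, `[[`, character(1), "kind"),
    admission_id = vapply(msgs, `[[`, character(1), "admission_id"),
    timestamp = as.POSIXct(vapply(msgs, function(m) as.numeric(m$timestamp),
                                  numeric(1)), origin = "1970-01-01", tz = "UTC"),
    payload = I(lapply(msgs, `[[`, "payload")),
    stringsAsFactors = FALSE
  )
}

df_to_messages <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    message_event(df$kind[i], df$admission_id[i], df$timestamp[i],
                  df$payload[[i]]))
}

#' Read and write newline-delimited JSON message streams
#'
#' One JSON object per line with keys `kind`, `admission_id`, `timestamp`
#' and `payload`; timestamps are `"%Y-%m-%d %H:%M:%S"` (timezone-naive
#' local hospital time — replay only needs ordering).
#'
#' @param messages A message data.frame as returned by [simulate_cohort()].
#' @param path File path of the `.ndjson` stream.
#' @return `read_messages()` returns the message data.frame.
#' @export
write_messages <- function(messages, path) {
  lines <- vapply(seq_len(nrow(messages)), function(i) {
    jsonlite::toJSON(list(kind = messages$kind[i],
                          admission_id = messages$admission_id[i],
                          timestamp = format_time(messages$timestamp[i]),
                          payload = messages$payload[[i]]),
                     auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_messages
#' @export
read_messages <- function(path) {
  lines <- readLines(path)
  msgs <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    message_event(x$kind, x$admission_id, x$timestamp, x$payload)
  })
  messages_df(msgs)
}

#' Fold a message stream into a static replay store
#'
#' Produces the three-table store (`admissions`, `observations`,
#' `outcomes`) that [run_replay()] consumes. Observation rows carry one
#' field per row with its timestamp; admission demographics and ICD codes
#' come from admission messages, discharge times from discharge messages.
#'
#' @param messages Message data.frame.
#' @return A `wf_store`.
#' @export
as_store <- function(messages) {
  ord <- order(messages$timestamp)
  messages <- messages[ord, , drop = FALSE]
  kind <- messages$kind
  ids <- messages$admission_id
  ts_num <- as.numeric(messages$timestamp)
  payloads <- messages$payload

  ai <- which(kind == "admission")
  ai <- ai[!duplicated(ids[ai])]               # duplicate admission: idempotent
  pick_chr <- function(idx, f) vapply(payloads[idx], function(p)
    as.character(p[[f]] %||% NA_character_), character(1))
  admitted <- ts_num[ai]
  disch_map <- ts_num[kind == "discharge"]
  names(disch_map) <- ids[kind == "discharge"]
  admissions <- data.frame(
    admission_id = ids[ai],
    patient_id = pick_chr(ai, "patient_id"),
    age = as.integer(vapply(payloads[ai], function(p)
      as.numeric(p$age %||% NA), numeric(1))),
    sex = pick_chr(ai, "sex"),
    admitted = as.POSIXct(admitted, origin = "1970-01-01", tz = "UTC"),
    discharged = as.POSIXct(unname(disch_map[ids[ai]]),
                            origin = "1970-01-01", tz = "UTC"),
    primary_icd = pick_chr(ai, "primary_icd"),
    icd_codes = vapply(payloads[ai], function(p)
      paste(unlist(p$icd_codes), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)

  oi <- which(kind %in% c("lab", "vital", "imaging_report"))
  nfields <- vapply(payloads[oi], length, integer(1))
  observations <- data.frame(
    admission_id = rep(ids[oi], nfields),
    field = unlist(lapply(payloads[oi], names)) %||% character(0),
    value = vapply(unlist(payloads[oi], recursive = FALSE),
                   as.character, character(1)),
    timestamp = as.POSIXct(rep(ts_num[oi], nfields), origin = "1970-01-01",
                           tz = "UTC"),
    stringsAsFactors = FALSE)

  ui <- which(kind == "outcome")
  outcomes <- data.frame(
    admission_id = ids[ui],
    died = vapply(payloads[ui], function(p) isTRUE(p$died), logical(1)),
    timestamp = as.POSIXct(ts_num[ui], origin = "1970-01-01", tz = "UTC"),
    stringsAsFactors = FALSE)
  rownames(admissions) <- NULL
  new_store(admissions, observations, outcomes)
}

#' Construct a replay store from its three tables
#'
#' @param admissions data.frame: `admission_id`, `patient_id`, `age`,
#'   `sex`, `admitted`, `discharged`, `primary_icd`, `icd_codes`
#'   (`;`-separated).
#' @param observations data.frame: `admission_id`, `field`, `value`,
#'   `timestamp`.
#' @param outcomes data.frame: `admission_id`, `died`, `timestamp`.
#' @return A `wf_store`.
#' @export
new_store <- function(admissions, observations = NULL, outcomes = NULL) {
  structure(list(
    admissions = admissions,
    observations = observations %||% data.frame(
      admission_id = character(), field = character(), value = character(),
      timestamp = as.POSIXct(character(), tz = "UTC")),
    outcomes = outcomes %||% data.frame(
      admission_id = character(), died = logical(),
      timestamp = as.POSIXct(character(), tz = "UTC"))),
    class = "wf_store")
}

#' @export
print.wf_store <- function(x, ...) {
  cat(sprintf("<wf_store> %d admissions, %d observations, %d outcomes\n",
              nrow(x$admissions), nrow(x$observations), nrow(x$outcomes)))
  invisible(x)
}

#' Persist a replay store as delimited text or SQLite
#'
#' `write_store_csv()`/`read_store_csv()` use three delimited files
#' (`admissions`, `observations`, `outcomes`) under a directory;
#' `write_store_sqlite()`/`read_store_sqlite()` use one SQLite database
#' with the same three tables (requires the RSQLite package).
#'
#' @param store A `wf_store`.
#' @param dir Directory for the delimited files.
#' @param delim Field delimiter.
#' @param path SQLite database file.
#' @return The read functions return a `wf_store`.
#' @export
write_store_csv <- function(store, dir, delim = ",") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    df <- as.data.frame(df)
    for (cn in names(df)) if (inherits(df[[cn]], "POSIXct"))
      df[[cn]] <- format_time(df[[cn]])
    utils::write.table(df, file.path(dir, paste0(name, ".csv")), sep = delim,
                       row.names = FALSE, quote = TRUE, na = "")
  }
  wr(store$admissions, "admissions")
  wr(store$observations, "observations")
  wr(store$outcomes, "outcomes")
  invisible(dir)
}

#' @rdname write_store_csv
#' @export
read_store_csv <- function(dir, delim = ",") {
  rd <- function(name) utils::read.table(
    file.path(dir, paste0(name, ".csv")), sep = delim, header = TRUE,
    stringsAsFactors = FALSE, colClasses = "character", na.strings = "")
  adm <- rd("admissions")
  adm$age <- as.integer(adm$age)
  adm$admitted <- parse_time(adm$admitted)
  adm$discharged <- parse_time(adm$discharged)
  obs <- rd("observations")
  if (nrow(obs)) obs$timestamp <- parse_time(obs$timestamp)
  outc <- rd("outcomes")
  if (nrow(outc)) {
    outc$died <- as.logical(outc$died)
    outc$timestamp <- parse_time(outc$timestamp)
  }
  new_store(adm, obs, outc)
}

#' @rdname write_store_csv
#' @export
write_store_sqlite <- function(store, path) {
  if (!requireNamespace("RSQLite", quietly = TRUE))
    wf_abort("wf_config_error", "the RSQLite package is required for SQLite stores")
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  wr <- function(df, name) {
    df <- as.data.frame(df)
    for (cn in names(df)) if (inherits(df[[cn]], "POSIXct"))
      df[[cn]] <- format_time(df[[cn]])
    DBI::dbWriteTable(con, name, df, overwrite = TRUE)
  }
  wr(store$admissions, "admissions")
  wr(store$observations, "observations")
  wr(store$outcomes, "outcomes")
  invisible(path)
}

#' @rdname write_store_csv
#' @export
read_store_sqlite <- function(path) {
  if (!requireNamespace("RSQLite", quietly = TRUE))
    wf_abort("wf_config_error", "the RSQLite package is required for SQLite stores")
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  adm <- DBI::dbReadTable(con, "admissions")
  adm$admitted <- parse_time(adm$admitted)
  adm$discharged <- parse_time(adm$discharged)
  obs <- DBI::dbReadTable(con, "observations")
  if (nrow(obs)) obs$timestamp <- parse_time(obs$timestamp)
  obs$value <- as.character(obs$value)
  outc <- DBI::dbReadTable(con, "outcomes")
  if (nrow(outc)) {
    outc$died <- as.logical(outc$died)
    outc$timestamp <- parse_time(outc$timestamp)
  }
  new_store(adm, obs, outc)
}

# ---- broker queues ----------------------------------------------------------

#' Broker queue abstraction
#'
#' The engine pushes outbound records (journey completions, engine outcome
#' data) onto a queue. Two implementations are provided: an in-memory
#' queue and a file-backed queue writing newline-delimited JSON, standing
#' in for an external message transport.
#'
#' @param path File path for the file-backed queue.
#' @return A queue object for `queue_push()`/`queue_drain()`.
#' @export
in_memory_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$items <- list()
  class(q) <- "wf_queue"
  q
}

#' @rdname in_memory_queue
#' @export
file_queue <- function(path) {
  q <- new.env(parent = emptyenv())
  q$path <- path
  if (!file.exists(path)) file.create(path)
  class(q) <- c("wf_file_queue", "wf_queue")
  q
}

#' @param q A queue.
#' @param x A `wf_message` (or any JSON-serializable list).
#' @rdname in_memory_queue
#' @export
queue_push <- function(q, x) {
  if (inherits(q, "wf_file_queue")) {
    line <- jsonlite::toJSON(
      list(kind = x$kind, admission_id = x$admission_id,
           timestamp = format_time(x$timestamp), payload = x$payload),
      auto_unbox = TRUE, digits = NA, null = "null")
    cat(line, "\n", sep = "", file = q$path, append = TRUE)
  } else {
    q$items[[length(q$items) + 1L]] <- x
  }
  invisible(q)
}

#' @rdname in_memory_queue
#' @export
queue_drain <- function(q) {
  if (inherits(q, "wf_file_queue")) {
    lines <- readLines(q$path)
    writeLines(character(0), q$path)
    lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
      message_event(x$kind, x$admission_id, x$timestamp, x$payload)
    })
  } else {
    items <- q$items
    q$items <- list()
    items
  }
}
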