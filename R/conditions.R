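# Structured error conditions. Every error raised by the package carries a
# subclass of "wf_error" so callers (notably the engine, which must convert
# missing-data errors into journey pauses) can dispatch on the failure kind
# rather than parse messages.

wf_abort <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "wf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' @export
conditionMessage.wf_error <- function(c) c$message

abort_missing_field <- function(name) {
  wf_abort("wf_missing_field", sprintf("required field '%s' is missing", name),
           field = name)
}

abort_invalid_value <- function(name, reason) {
  wf_abort("wf_invalid_value",
           sprintf("invalid value for field '%s': %s", name, reason),
           field = name, reason = reason)
}

abort_schema_mismatch <- function(message, ...) {
  wf_abort("wf_schema_mismatch", message, ...)
}

is_wf_error <- function(x, class = "wf_error") inherits(x, class)
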