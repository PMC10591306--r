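#' Declare a data field
#'
#' A field is the unit of a [data_schema()]: a named, typed slot with an
#' optional unit, default and permitted range. Defaults are substituted by
#' [validate_record()] when the field is absent from a record; a field cannot
#' be both `required` and carry a `default`.
#'
#' @param name Field identifier (non-empty string).
#' @param kind One of `"number"`, `"integer"`, `"boolean"`, `"text"`,
#'   `"datetime"`, `"category"`.
#' @param unit Free-text unit, e.g. `"mmol/L"`, `"mmHg"`, `"breaths/min"`.
#' @param required If `TRUE`, [validate_record()] raises a missing-field
#'   error when the field is absent.
#' @param default Value used when the field is absent and not required.
#'   Must itself satisfy `kind` and `range`/`choices`.
#' @param range Closed numeric interval `c(lo, hi)` for number/integer
#'   fields.
#' @param choices Permitted values for category fields.
#' @return An object of class `wf_field`.
#' @export
#' @examples
#' data_field("urea", "number", unit = "mmol/L", required = TRUE)
#' data_field("crp", "number", unit = "mg/L", default = 0)
data_field <- function(name, kind = "number", unit = NULL, required = FALSE,
                       default = NULL, range = NULL, choices = NULL) {
  kinds <- c("number", "integer", "boolean", "text", "datetime", "category")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    wf_abort("wf_config_error", "field name must be a non-empty string")
  if (!kind %in% kinds)
    wf_abort("wf_config_error",
             sprintf("unknown field kind '%s' for '%s'", kind, name))
  if (required && !is.null(default))
    wf_abort("wf_config_error",
             sprintf("field '%s': required and default are mutually exclusive",
                     name))
  if (!is.null(range) && (!is.numeric(range) || length(range) != 2L ||
                          range[1] > range[2]))
    wf_abort("wf_config_error",
             sprintf("field '%s': range must be c(lo, hi)", name))
  f <- structure(
    list(name = name, kind = kind, unit = unit, required = required,
         default = default, range = range, choices = choices),
    class = "wf_field"
  )
  if (!is.null(default)) {
    # the default must itself validate; coerce it once here
    f$default <- coerce_value(default, f)
  }
  f
}

#' Declare a data schema
#'
#' An ordered collection of [data_field()]s with a version tag. Schemas sit
#' in front of every algorithm and data source: records are validated and
#' coerced against a schema before use, which prevents a data set being run
#' through an algorithm whose inputs it does not satisfy.
#'
#' @param name Schema identifier.
#' @param fields List of [data_field()] objects; names must be unique.
#' @param version Version tag, compared by exact string match when a
#'   serialized algorithm is loaded against supplied data.
#' @return An object of class `wf_schema`.
#' @export
data_schema <- function(name, fields, version = "1") {
  if (length(fields) == 0L)
    wf_abort("wf_config_error", "a schema needs at least one field")
  if (inherits(fields, "wf_field")) fields <- list(fields)
  ok <- vapply(fields, inherits, logical(1), what = "wf_field")
  if (!all(ok))
    wf_abort("wf_config_error", "schema fields must be data_field objects")
  nms <- vapply(fields, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    wf_abort("wf_config_error",
             sprintf("duplicate field name(s): %s",
                     paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  names(fields) <- nms
  structure(list(name = name, fields = fields, version = as.character(version)),
            class = "wf_schema")
}

#' @export
print.wf_schema <- function(x, ...) {
  cat(sprintf("<wf_schema> %s (v%s)\n", x$name, x$version))
  for (f in x$fields) {
    cat(sprintf("  %-14s %-8s%s%s%s\n", f$name, f$kind,
                if (f$required) " required" else "",
                if (!is.null(f$default)) sprintf(" default=%s", format(f$default)) else "",
                if (!is.null(f$unit)) sprintf(" [%s]", f$unit) else ""))
  }
  invisible(x)
}

schema_field_names <- function(schema) names(schema$fields)

# Coerce a scalar to a field's declared kind, enforcing range/choices.
# Raises wf_invalid_value on failure. NULL/NA are handled by the caller.
coerce_value <- function(value, field) {
  name <- field$name
  v <- switch(
    field$kind,
    number = {
      x <- suppressWarnings(as.numeric(value))
      if (length(x) != 1L || is.na(x))
        abort_invalid_value(name, sprintf("'%s' is not numeric", format(value)))
      x
    },
    integer = {
      x <- suppressWarnings(as.numeric(value))
      if (length(x) != 1L || is.na(x) || x != round(x))
        abort_invalid_value(name, sprintf("'%s' is not an integer", format(value)))
      as.integer(x)
    },
    boolean = {
      x <- value
      if (is.character(x))
        x <- switch(tolower(x), "true" = TRUE, "t" = TRUE, "1" = TRUE,
                    "yes" = TRUE, "false" = FALSE, "f" = FALSE, "0" = FALSE,
                    "no" = FALSE, NA)
      if (is.numeric(x) && x %in% c(0, 1)) x <- as.logical(x)
      if (!is.logical(x) || length(x) != 1L || is.na(x))
        abort_invalid_value(name, sprintf("'%s' is not boolean", format(value)))
      x
    },
    text = {
      if (length(value) != 1L)
        abort_invalid_value(name, "text field expects a single value")
      as.character(value)
    },
    datetime = {
      x <- value
      if (!inherits(x, "POSIXct")) {
        x <- suppressWarnings(
          as.POSIXct(as.character(value), tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                                    "%Y-%m-%d %H:%M", "%Y-%m-%d")))
      }
      if (length(x) != 1L || is.na(x))
        abort_invalid_value(name, sprintf("'%s' is not a datetime", format(value)))
      x
    },
    category = {
      x <- as.character(value)
      if (length(x) != 1L || is.na(x))
        abort_invalid_value(name, "category field expects a single value")
      x
    }
  )
  if (!is.null(field$range) && field$kind %in% c("number", "integer")) {
    if (v < field$range[1] || v > field$range[2])
      abort_invalid_value(name, sprintf("%s outside range [%s, %s]",
                                        format(v), field$range[1], field$range[2]))
  }
  if (!is.null(field$choices) && field$kind %in% c("category", "text")) {
    if (!v %in% field$choices)
      abort_invalid_value(name, sprintf("'%s' not one of {%s}", v,
                                        paste(field$choices, collapse = ", ")))
  }
  v
}

#' Validate and coerce a record against a schema
#'
#' Values are coerced to each field's declared kind (numeric text such as
#' `"8.1"` becomes `8.1`), defaults are substituted for absent non-required
#' fields, and ranges/choice sets are enforced. Validation is idempotent:
#' validating an already-validated record returns it unchanged.
#'
#' @param schema A [data_schema()].
#' @param record A flat named list (or named vector) of field values.
#' @return A named list with one validated entry per schema field that is
#'   present, required, or defaulted.
#' @export
#' @examples
#' sch <- data_schema("bloods", list(
#'   data_field("urea", "number", required = TRUE),
#'   data_field("crp", "number", default = 0)))
#' validate_record(sch, list(urea = "8.1"))
validate_record <- function(schema, record) {
  stopifnot(inherits(schema, "wf_schema"))
  record <- as.list(record)
  out <- list()
  for (f in schema$fields) {
    v <- record[[f$name]]
    if (is.null(v) || (length(v) == 1L && is.na(v) && f$kind != "boolean") ||
        (length(v) == 1L && is.logical(v) && is.na(v))) {
      if (!is.null(f$default)) {
        out[[f$name]] <- f$default
      } else if (f$required) {
        abort_missing_field(f$name)
      }
      # optional and absent: omitted from the validated record
    } else {
      out[[f$name]] <- coerce_value(v, f)
    }
  }
  out
}
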