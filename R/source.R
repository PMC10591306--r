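#' Declare a data source
#'
#' A data source names where a step's input comes from and which schema the
#' delivered records must satisfy. Transforms are record-level functions
#' (`function(record) record`) applied in declared order before validation,
#' used for on-the-fly conversion of non-standard formats (date parsing,
#' unit conversion, diagnosis coding). A source with `constituents` is a
#' collated source: its record is the field-wise merge of its children's
#' records (see [collate()]).
#'
#' @param name Source identifier.
#' @param schema The [data_schema()] delivered records must satisfy.
#' @param transforms Ordered list of `function(record) record`.
#' @param constituents Optional list of child `data_source` objects.
#' @return An object of class `wf_source`.
#' @export
data_source <- function(name, schema, transforms = list(), constituents = list()) {
  stopifnot(inherits(schema, "wf_schema"))
  if (length(transforms) && !all(vapply(transforms, is.function, logical(1))))
    wf_abort("wf_config_error", "transforms must be functions")
  if (length(constituents) &&
      !all(vapply(constituents, inherits, logical(1), what = "wf_source")))
    wf_abort("wf_config_error", "constituents must be data_source objects")
  structure(list(name = name, schema = schema, transforms = transforms,
                 constituents = constituents),
            class = "wf_source")
}

apply_transforms <- function(source, record) {
  for (fn in source$transforms) record <- fn(record)
  record
}

#' Merge records from several sources into one validated record
#'
#' Records are merged in source order with **last source wins** on a field
#' name collision (the precedence is deterministic and follows the declared
#' order), transformed per source, and the merged record is validated
#' against `schema`. Over sources with disjoint fields the merge is
#' associative.
#'
#' @param sources List of [data_source()] objects.
#' @param records List of records, one per source (possibly empty lists).
#' @param schema Schema of the collated result; defaults to the union of the
#'   source schemas' fields (later sources override on duplicate names).
#' @return A validated record (named list).
#' @export
collate <- function(sources, records, schema = NULL) {
  if (length(sources) != length(records))
    wf_abort("wf_config_error", "one record per source is required")
  merged <- list()
  for (i in seq_along(sources)) {
    rec <- apply_transforms(sources[[i]], as.list(records[[i]]))
    for (nm in names(rec)) merged[[nm]] <- rec[[nm]]
  }
  if (is.null(schema)) schema <- union_schema(sources)
  validate_record(schema, merged)
}

# Union of constituent schemas; later sources override duplicate field names.
union_schema <- function(sources, name = "collated", version = "1") {
  fields <- list()
  for (s in sources) for (f in s$schema$fields) fields[[f$name]] <- f
  data_schema(name, unname(fields), version = version)
}

# Resolve a (possibly collated) source to the flat list of leaf sources,
# in declared order.
leaf_sources <- function(source) {
  if (length(source$constituents) == 0L) return(list(source))
  out <- list()
  for (child in source$constituents) out <- c(out, leaf_sources(child))
  out
}

# Fetch a record for `source` from per-leaf-source records and collate it
# against the source's own schema.
collate_source <- function(source, records_by_name) {
  leaves <- leaf_sources(source)
  records <- lapply(leaves, function(s) records_by_name[[s$name]] %||% list())
  out <- collate(leaves, records, schema = source$schema)
  apply_transforms(source, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
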