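# Plugin registry: IRIs are the dispatch keys. Data Plugins generate
# synthetic values for one atomic-type IRI; Database Plugins provision one
# source-technology IRI as an embedded loopback backend. Registration is
# injective -- each IRI is bound to exactly one plugin.

#' Create an empty plugin registry
#' @return an object of class `fs_plugin_registry`.
#' @export
plugin_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$bindings <- new.env(parent = emptyenv())
  class(reg) <- "fs_plugin_registry"
  reg
}

#' Define a Data Plugin
#'
#' @param iri the atomic-type IRI the plugin serves.
#' @param generate `function(params, stream)` returning one synthetic value;
#'   must be pure given the generation parameters and the stream state.
#' @param check `function(value, params)` returning `TRUE` iff a value
#'   conforms to the plugin's type contract (used by type-conformity sweeps).
#' @return an object of class `fs_data_plugin`.
#' @export
data_type_plugin <- function(iri, generate, check = function(value, params) TRUE) {
  stopifnot(is_valid_iri(iri), is.function(generate), is.function(check))
  structure(list(iri = iri, generate = generate, check = check), class = c("fs_data_plugin", "fs_plugin"))
}

#' Define a Database Plugin
#'
#' The embedded backends ship with the package and are selected by
#' `backend`; the plugin object records which backend provisions sources of
#' its technology IRI. An external plugin may supply its own `provision`.
#'
#' @param iri the source-technology IRI the plugin serves.
#' @param backend backend key: `"relational"`, `"document"`, `"objectstore"`
#'   or `"fhir"`.
#' @return an object of class `fs_source_plugin`.
#' @export
data_source_plugin <- function(iri, backend) {
  stopifnot(is_valid_iri(iri), is_string(backend))
  structure(list(iri = iri, backend = backend), class = c("fs_source_plugin", "fs_plugin"))
}

#' Register a plugin under its IRI
#' @param registry a [plugin_registry()].
#' @param plugin a Data or Database Plugin.
#' @return the registry, invisibly (registration is by reference).
#' @export
register_plugin <- function(registry, plugin) {
  stopifnot(inherits(registry, "fs_plugin_registry"), inherits(plugin, "fs_plugin"))
  if (!is.null(registry$bindings[[plugin$iri]])) {
    fs_abort("duplicate_binding", sprintf("IRI <%s> is already bound to a plugin", plugin$iri))
  }
  registry$bindings[[plugin$iri]] <- plugin
  invisible(registry)
}

#' Resolve the plugin bound to an IRI
#' @param registry a [plugin_registry()].
#' @param iri the dispatch IRI.
#' @return the unique plugin bound to `iri`.
#' @export
resolve_plugin <- function(registry, iri) {
  stopifnot(inherits(registry, "fs_plugin_registry"))
  pl <- registry$bindings[[iri]]
  if (is.null(pl)) fs_abort("unresolved_iri", sprintf("no plugin registered for IRI <%s>", iri))
  pl
}

#' List all IRIs bound in a registry
#' @param registry a [plugin_registry()].
#' @return character vector of bound IRIs.
#' @export
registered_iris <- function(registry) sort(ls(registry$bindings))

#' Generate one synthetic value through a Data Plugin
#'
#' @param plugin an `fs_data_plugin`.
#' @param params generation parameters (see [attribute_spec()]).
#' @param stream an [random_stream()] supplying all randomness.
#' @return a synthetic value conforming to the plugin's type contract.
#' @export
generate_value <- function(plugin, params, stream) {
  stopifnot(inherits(plugin, "fs_data_plugin"), inherits(stream, "fs_random_stream"))
  params <- params %||% list()
  if (!is.null(params$min) && !is.null(params$max) && params$min > params$max) {
    fs_abort("invalid_params", "min > max")
  }
  if (!is.null(params$null_prob) && (params$null_prob < 0 || params$null_prob > 1)) {
    fs_abort("invalid_params", "null_prob outside [0, 1]")
  }
  plugin$generate(params, stream)
}

gen_uuid <- function(stream) {
  paste(rs_hex(stream, 8), rs_hex(stream, 4), rs_hex(stream, 4),
        rs_hex(stream, 4), rs_hex(stream, 12), sep = "-")
}

gen_date <- function(stream, from = "2000-01-01", to = "2024-12-31") {
  d0 <- as.integer(as.Date(from)); d1 <- as.integer(as.Date(to))
  format(as.Date(rs_int(stream, d0, d1), origin = "1970-01-01"), "%Y-%m-%d")
}

gen_jpeg <- function(params, stream) {
  w <- as.integer(params$width %||% 64L)
  h <- as.integer(params$height %||% 64L)
  px <- rs_unif(stream, 0, 1, n = w * h * 3L)
  jpeg::writeJPEG(array(px, dim = c(h, w, 3L)), raw(), quality = 0.8)
}

is_jpeg_bytes <- function(x) is.raw(x) && length(x) > 2 && identical(x[1:2], as.raw(c(0xFF, 0xD8)))

gen_fhir <- function(resource_type) {
  function(params, stream) {
    res <- list(resourceType = resource_type, id = gen_uuid(stream))
    switch(resource_type,
      Patient = {
        res$gender <- rs_pick(stream, c("male", "female", "other", "unknown"))
        res$birthDate <- gen_date(stream, "1930-01-01", "2010-12-31")
      },
      Media = {
        res$status <- "completed"
        res$type <- list(text = "image")
      },
      ImagingStudy = {
        res$status <- "available"
        res$description <- "dermoscopic imaging study"
      })
    res
  }
}

is_fhir_resource <- function(x, type) is.list(x) && identical(x$resourceType, type) && is_string(x$id)

builtin_data_plugins <- function() {
  list(
    data_type_plugin(fs_iri("integer"),
      generate = function(params, stream) rs_int(stream, as.integer(params$min %||% 0), as.integer(params$max %||% 100)),
      check = function(v, p) is.numeric(v) && v == as.integer(v) &&
        v >= (p$min %||% 0) && v <= (p$max %||% 100)),
    data_type_plugin(fs_iri("double"),
      generate = function(params, stream) rs_unif(stream, params$min %||% 0, params$max %||% 100),
      check = function(v, p) is.numeric(v) && v >= (p$min %||% 0) && v <= (p$max %||% 100)),
    data_type_plugin(fs_iri("string"),
      generate = function(params, stream) rs_chars(stream, as.integer(params$length %||% 12L)),
      check = function(v, p) is_string(v) && nchar(v) == (p$length %||% 12L)),
    data_type_plugin(fs_iri("boolean"),
      generate = function(params, stream) rs_pick(stream, c(TRUE, FALSE)),
      check = function(v, p) is.logical(v) && length(v) == 1L),
    data_type_plugin(fs_iri("date"),
      generate = function(params, stream) gen_date(stream),
      check = function(v, p) is_string(v) && grepl("^\\d{4}-\\d{2}-\\d{2}$", v)),
    data_type_plugin(fs_iri("datetime"),
      generate = function(params, stream) paste0(gen_date(stream), "T", sprintf("%02d:%02d:%02d",
        rs_int(stream, 0, 23), rs_int(stream, 0, 59), rs_int(stream, 0, 59))),
      check = function(v, p) is_string(v) && grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", v)),
    data_type_plugin(fs_iri("categorical"),
      generate = function(params, stream) rs_pick(stream, params$choices %||% c("a", "b", "c")),
      check = function(v, p) is_string(v) && v %in% (p$choices %||% c("a", "b", "c"))),
    data_type_plugin(fs_iri("uuid"),
      generate = function(params, stream) gen_uuid(stream),
      check = function(v, p) is_string(v) && grepl("^[0-9a-f]{8}(-[0-9a-f]{4}){3}-[0-9a-f]{12}$", v)),
    data_type_plugin(fs_iri("jpeg"),
      generate = gen_jpeg,
      check = function(v, p) is_jpeg_bytes(v)),
    data_type_plugin(fs_iri("fhir-Patient"), gen_fhir("Patient"),
      check = function(v, p) is_fhir_resource(v, "Patient")),
    data_type_plugin(fs_iri("fhir-Media"), gen_fhir("Media"),
      check = function(v, p) is_fhir_resource(v, "Media")),
    data_type_plugin(fs_iri("fhir-ImagingStudy"), gen_fhir("ImagingStudy"),
      check = function(v, p) is_fhir_resource(v, "ImagingStudy"))
  )
}

builtin_source_plugins <- function() {
  lapply(c("relational", "document", "objectstore", "fhir"), function(b) {
    data_source_plugin(fs_iri(b), backend = b)
  })
}

#' Registry with all built-in plugins registered
#'
#' Binds the 12 built-in Data Plugins (one per atomic-type IRI of the
#' vocabulary) and the 4 embedded Database Plugins (relational, document,
#' object store, FHIR-like).
#'
#' @return an `fs_plugin_registry`.
#' @export
default_registry <- function() {
  reg <- plugin_registry()
  for (pl in c(builtin_data_plugins(), builtin_source_plugins())) register_plugin(reg, pl)
  reg
}
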