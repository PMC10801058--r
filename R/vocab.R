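#' The fedsmoke schema vocabulary
#'
#' Provider data sources are modeled in RDF under a single versioned
#' namespace. Classes describe the hierarchy (Provider, DataSource, Entity,
#' Attribute), predicates connect it (`hasSource`, `hasEntity`,
#' `hasAttribute`, `technology`, `datatype`, `linksTo`), and IRIs under the
#' same namespace name the atomic data types dispatched to Data Plugins and
#' the source technologies dispatched to Database Plugins. The vocabulary is
#' shipped as Turtle in `inst/extdata/vocabulary.ttl`.
#'
#' @name fs_vocab
NULL

FS_NS <- "http://fedsmoke.org/vocab#"
FS_NODE_NS <- "http://fedsmoke.org/model/"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

#' Build an IRI in the fedsmoke vocabulary namespace
#' @param local local name, e.g. `"integer"`.
#' @return the absolute IRI string.
#' @export
fs_iri <- function(local) paste0(FS_NS, local)

#' Validate an absolute IRI
#' @param x a character scalar.
#' @return `TRUE` if `x` is a non-empty absolute IRI (has a scheme).
#' @export
is_valid_iri <- function(x) {
  is_string(x) && grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) && !grepl("[ \t\n<>\"{}|\\\\^`]", x)
}

# Atomic data-type IRIs (Data Plugins).
fs_type_iris <- function() {
  fs_iri(c("integer", "double", "string", "boolean", "date", "datetime",
           "categorical", "uuid", "jpeg", "fhir-Patient", "fhir-Media",
           "fhir-ImagingStudy"))
}

# Source-technology IRIs (Database Plugins).
fs_technology_iris <- function() {
  fs_iri(c("relational", "document", "objectstore", "fhir"))
}

fs_classes <- function() fs_iri(c("Provider", "DataSource", "Entity", "Attribute"))

fs_predicates <- function() {
  fs_iri(c("hasSource", "hasEntity", "hasAttribute", "technology", "datatype",
           "linksTo", "name", "index", "genMin", "genMax", "genChoices",
           "genNullProb", "genLength", "genWidth", "genHeight"))
}

#' Path to the shipped vocabulary Turtle file
#' @return file path of `vocabulary.ttl`.
#' @export
fs_vocabulary_path <- function() {
  system.file("extdata", "vocabulary.ttl", package = "fedsmoke", mustWork = TRUE)
}
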