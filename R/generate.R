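# Seeded synthetic dataset generation for one provider schema.
#
# Each (provider, source, entity) gets its own random stream derived from
# the root seed, so values do not depend on generation order. Entities are
# generated in link-dependency order; link attributes then reference
# identifiers of already-generated target records, and FHIR resource values
# are wired to the records their link attributes point at (subject
# references to Patients, content URLs to object-store blobs).

topo_entities <- function(schema) {
  nodes <- list()
  for (src in schema$sources) for (ent in src$entities) {
    nodes[[paste(src$name, ent$name, sep = "/")]] <- list(source = src$name, entity = ent)
  }
  deps <- lapply(nodes, function(nd) {
    links <- Filter(Negate(is.null), lapply(nd$entity$attributes, `[[`, "links_to"))
    vapply(links, function(l) paste(l$source, l$entity, sep = "/"), "")
  })
  ordered <- character(0)
  remaining <- names(nodes)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(k) all(deps[[k]] %in% ordered), TRUE)]
    if (!length(ready)) fs_abort("invalid_schema", "cyclic link structure between entities")
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  nodes[ordered]
}

record_id <- function(entity_name, i) sprintf("%s-%04d", entity_name, i)

#' Generate a seeded synthetic dataset for a provider
#'
#' @param schema a validated [provider_schema()].
#' @param n_per_entity positive integer: records generated per entity.
#' @param seed integer root seed; identical `(schema, n, seed)` yields a
#'   byte-identical dataset including blobs.
#' @param registry a [plugin_registry()] resolving every type IRI.
#' @return an object of class `fs_dataset`: `records[[source]][[entity]]` is
#'   a list of named record lists (each with an implicit `` `_id` ``),
#'   `blobs` maps object keys to raw JPEG bytes.
#' @export
generate_dataset <- function(schema, n_per_entity, seed, registry) {
  stopifnot(inherits(schema, "fs_provider_schema"))
  if (!is_count(n_per_entity)) fs_abort("invalid_params", "n_per_entity must be a positive integer")
  diags <- validate_provider_schema(schema, registry)
  if (nrow(diags)) {
    fs_abort("invalid_schema", paste("schema failed validation:", paste(diags$message, collapse = "; ")))
  }
  n <- as.integer(n_per_entity)
  records <- list()
  blobs <- list()
  for (src in schema$sources) records[[src$name]] <- list()

  for (node in topo_entities(schema)) {
    src_name <- node$source
    ent <- node$entity
    stream <- random_stream(derive_seed(seed, schema$provider_id, src_name, ent$name))
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      rec <- list(`_id` = record_id(ent$name, i))
      for (at in ent$attributes) {
        if (!is.null(at$links_to)) {
          targets <- records[[at$links_to$source]][[at$links_to$entity]]
          rec[[at$name]] <- targets[[rs_int(stream, 1L, length(targets))]][["_id"]]
          next
        }
        if (!is.null(at$params$null_prob) && rs_flip(stream, at$params$null_prob)) {
          rec[at$name] <- list(NULL)
          next
        }
        plugin <- resolve_plugin(registry, at$type_iri)
        val <- generate_value(plugin, at$params, stream)
        if (is_jpeg_bytes(val)) {
          key <- sprintf("%s/%s/%s-%04d.jpg", src_name, ent$name, at$name, i)
          blobs[[key]] <- val
          val <- key
        }
        rec[[at$name]] <- val
      }
      recs[[i]] <- rec
    }
    records[[src_name]][[ent$name]] <- recs
  }

  dataset <- structure(list(provider_id = schema$provider_id, seed = seed,
                            n_per_entity = n, records = records, blobs = blobs),
                       class = "fs_dataset")
  wire_fhir_references(dataset, schema)
}

# Inject minimal FHIR reference structure: a resource-valued record whose
# sibling link attribute targets a Patient entity gains subject.reference
# "Patient/<id>"; one targeting a record with a blob-keyed attribute gains
# content.url "objects/<key>". Structure only -- no claim of full FHIR
# conformance.
wire_fhir_references <- function(dataset, schema) {
  index_by_id <- function(src, entname) {
    recs <- dataset$records[[src]][[entname]]
    names(recs) <- vapply(recs, `[[`, "", "_id")
    recs
  }
  for (src in schema$sources) for (ent in src$entities) {
    res_attrs <- Filter(function(a) grepl("#fhir-", a$type_iri, fixed = TRUE), ent$attributes)
    link_attrs <- Filter(function(a) !is.null(a$links_to), ent$attributes)
    if (!length(res_attrs) || !length(link_attrs)) next
    recs <- dataset$records[[src$name]][[ent$name]]
    for (k in seq_along(recs)) {
      rec <- recs[[k]]
      for (ra in res_attrs) {
        res <- rec[[ra$name]]
        res$id <- rec[["_id"]]
        for (la in link_attrs) {
          target <- index_by_id(la$links_to$source, la$links_to$entity)[[rec[[la$name]]]]
          tgt_ent <- find_entity(schema, la$links_to$source, la$links_to$entity)
          tgt_res_attr <- Filter(function(a) identical(a$type_iri, fs_iri("fhir-Patient")), tgt_ent$attributes)
          tgt_blob_attr <- Filter(function(a) identical(a$type_iri, fs_iri("jpeg")), tgt_ent$attributes)
          if (length(tgt_res_attr)) {
            res$subject <- list(reference = paste0("Patient/", target[["_id"]]))
          }
          if (length(tgt_blob_attr)) {
            res$content <- list(url = paste0("objects/", target[[tgt_blob_attr[[1]]$name]]),
                                contentType = "image/jpeg")
          }
        }
        rec[[ra$name]] <- res
      }
      recs[[k]] <- rec
    }
    dataset$records[[src$name]][[ent$name]] <- recs
  }
  dataset
}

#' Content digest of a dataset (blobs included)
#' @param dataset an `fs_dataset`.
#' @return MD5 hex digest of the canonical serialized dataset.
#' @export
dataset_digest <- function(dataset) {
  stopifnot(inherits(dataset, "fs_dataset"))
  blob_sums <- lapply(dataset$blobs, md5_raw)
  if (length(blob_sums)) blob_sums <- blob_sums[order(names(blob_sums))]
  md5_string(canonical_json(list(provider_id = dataset$provider_id, seed = dataset$seed,
                                 n = dataset$n_per_entity, records = dataset$records,
                                 blobs = blob_sums)))
}

#' Count of records per entity in a dataset
#' @param dataset an `fs_dataset`.
#' @return named integer vector `source/entity` -> record count.
#' @export
dataset_counts <- function(dataset) {
  out <- integer(0)
  for (src in names(dataset$records)) for (ent in names(dataset$records[[src]])) {
    out[[paste(src, ent, sep = "/")]] <- length(dataset$records[[src]][[ent]])
  }
  out
}

#' Dump a dataset to disk for inspection
#'
#' Tabular entities (all-scalar records) become CSV, others NDJSON; blobs
#' are written as files under `blobs/`.
#'
#' @param dataset an `fs_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
dump_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (src in names(dataset$records)) {
    for (ent in names(dataset$records[[src]])) {
      recs <- dataset$records[[src]][[ent]]
      scalar <- all(vapply(recs, function(r) all(vapply(r, function(v) is.null(v) || (is.atomic(v) && length(v) == 1L), TRUE)), TRUE))
      base <- file.path(dir, src)
      dir.create(base, showWarnings = FALSE, recursive = TRUE)
      if (scalar) {
        df <- do.call(rbind, lapply(recs, function(r) {
          as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v), stringsAsFactors = FALSE)
        }))
        utils::write.csv(df, file.path(base, paste0(ent, ".csv")), row.names = FALSE)
      } else {
        con <- file(file.path(base, paste0(ent, ".ndjson")), "w")
        for (r in recs) writeLines(canonical_json(r), con)
        close(con)
      }
    }
  }
  if (length(dataset$blobs)) {
    for (key in names(dataset$blobs)) {
      path <- file.path(dir, "blobs", key)
      dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
      writeBin(dataset$blobs[[key]], path)
    }
  }
  invisible(dir)
}
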