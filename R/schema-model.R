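# Provider schema model: typed description of each data provider's sources,
# entities and attributes, serialized as RDF/Turtle under the fedsmoke
# vocabulary. Every attribute carries exactly one atomic-type IRI and every
# source exactly one technology IRI; these IRIs are the dispatch keys that
# bind the schema to Data Plugins and Database Plugins.

ID_RE <- "^[A-Za-z][A-Za-z0-9_-]*$"

check_identifier <- function(x, what) {
  if (!is_string(x) || !grepl(ID_RE, x)) {
    fs_abort("invalid_schema", sprintf("%s must match %s, got %s", what, ID_RE,
                                       deparse(substitute(x, env = parent.frame()))))
  }
  x
}

#' Attribute specification
#'
#' @param name attribute identifier, unique within its entity.
#' @param type_iri atomic data-type IRI (see [fs_iri()]); dispatched to a
#'   Data Plugin at generation time.
#' @param params optional generation parameters: `min`/`max` (numeric range),
#'   `choices` (categorical levels), `null_prob` (probability of `NA`),
#'   `length` (string length), `width`/`height` (image size in pixels).
#' @param links_to optional `list(source =, entity =)` naming an entity of
#'   the same provider this attribute references (foreign-key-like arc);
#'   generated values are then identifiers of target records.
#' @return an object of class `fs_attribute`.
#' @export
attribute_spec <- function(name, type_iri, params = list(), links_to = NULL) {
  if (!is_string(name) || !grepl(ID_RE, name)) fs_abort("invalid_schema", sprintf("attribute name '%s' is not a valid identifier", name))
  if (!is_valid_iri(type_iri)) fs_abort("invalid_schema", sprintf("attribute '%s' needs an absolute type IRI", name))
  if (!is.null(params$null_prob) && (params$null_prob < 0 || params$null_prob > 1)) {
    fs_abort("invalid_params", "null_prob must be in [0, 1]")
  }
  if (!is.null(params$min) && !is.null(params$max) && params$min > params$max) {
    fs_abort("invalid_params", sprintf("attribute '%s': min > max", name))
  }
  if (!is.null(links_to)) stopifnot(is_string(links_to$source), is_string(links_to$entity))
  structure(list(name = name, type_iri = type_iri, params = params, links_to = links_to),
            class = "fs_attribute")
}

#' Entity specification (table / collection / resource type)
#' @param name entity identifier.
#' @param attributes list of [attribute_spec()] objects, at least one; names
#'   must be unique within the entity.
#' @return an object of class `fs_entity`.
#' @export
entity_spec <- function(name, attributes) {
  if (!is_string(name) || !grepl(ID_RE, name)) fs_abort("invalid_schema", sprintf("entity name '%s' is not a valid identifier", name))
  if (!length(attributes)) fs_abort("invalid_schema", sprintf("entity '%s' needs at least one attribute", name))
  stopifnot(all(vapply(attributes, inherits, TRUE, "fs_attribute")))
  nm <- vapply(attributes, `[[`, "", "name")
  if (anyDuplicated(nm)) fs_abort("invalid_schema", sprintf("entity '%s' has duplicate attribute names", name))
  structure(list(name = name, attributes = attributes), class = "fs_entity")
}

#' Data source specification
#' @param name source identifier, unique within its provider.
#' @param technology_iri source-technology IRI dispatched to a Database
#'   Plugin at provisioning time (e.g. `fs_iri("relational")`).
#' @param entities list of [entity_spec()] objects.
#' @return an object of class `fs_source_spec`.
#' @export
data_source_spec <- function(name, technology_iri, entities) {
  if (!is_string(name) || !grepl(ID_RE, name)) fs_abort("invalid_schema", sprintf("source name '%s' is not a valid identifier", name))
  if (!is_valid_iri(technology_iri)) fs_abort("invalid_schema", sprintf("source '%s' needs an absolute technology IRI", name))
  stopifnot(length(entities) >= 1, all(vapply(entities, inherits, TRUE, "fs_entity")))
  if (anyDuplicated(vapply(entities, `[[`, "", "name"))) {
    fs_abort("invalid_schema", sprintf("source '%s' has duplicate entity names", name))
  }
  structure(list(name = name, technology_iri = technology_iri, entities = entities),
            class = "fs_source_spec")
}

#' Provider schema
#' @param provider_id provider identifier, unique within a schema document.
#' @param sources list of [data_source_spec()] objects (possibly interlinked,
#'   e.g. a FHIR-like server plus an object store).
#' @return an object of class `fs_provider_schema`.
#' @export
provider_schema <- function(provider_id, sources) {
  if (!is_string(provider_id) || !grepl(ID_RE, provider_id)) {
    fs_abort("invalid_schema", sprintf("provider id '%s' is not a valid identifier", provider_id))
  }
  stopifnot(length(sources) >= 1, all(vapply(sources, inherits, TRUE, "fs_source_spec")))
  if (anyDuplicated(vapply(sources, `[[`, "", "name"))) {
    fs_abort("invalid_schema", sprintf("provider '%s' has duplicate source names", provider_id))
  }
  structure(list(provider_id = provider_id, sources = sources), class = "fs_provider_schema")
}

node_iri <- function(...) paste0(FS_NODE_NS, paste(c(...), collapse = "/"))

# plain-list canonical form used for structural (round-trip) comparison
schema_canonical <- function(schemas) {
  strip <- function(x) {
    if (inherits(x, "fs_attribute")) {
      prm <- x$params
      if (length(prm)) prm <- prm[order(names(prm))]
      list(name = x$name, type_iri = x$type_iri, params = prm, links_to = x$links_to)
    } else if (inherits(x, "fs_entity")) {
      list(name = x$name, attributes = lapply(x$attributes, strip))
    } else if (inherits(x, "fs_source_spec")) {
      list(name = x$name, technology_iri = x$technology_iri, entities = lapply(x$entities, strip))
    } else {
      list(provider_id = x$provider_id, sources = lapply(x$sources, strip))
    }
  }
  canonical_json(lapply(schemas, strip))
}

#' Structural equality of provider schema lists
#' @param a,b lists of [provider_schema()] objects.
#' @return `TRUE` if the structural content is identical.
#' @export
schemas_equal <- function(a, b) identical(schema_canonical(a), schema_canonical(b))

fmt_num <- function(x) {
  if (is.numeric(x) && x == as.integer(x)) sprintf("%d", as.integer(x)) else format(x, scientific = FALSE, trim = TRUE)
}

#' Serialize provider schemas as Turtle
#'
#' Emits the fedsmoke vocabulary form of the schemas. Providers, sources,
#' entities and attributes are written in declaration order and carry an
#' `fs:index` literal, so parsing the output reconstructs the original
#' structure exactly and repeated serialization is byte-identical.
#'
#' @param schemas list of [provider_schema()] objects.
#' @return Turtle document as a character scalar.
#' @export
serialize_provider_schemas <- function(schemas) {
  stopifnot(all(vapply(schemas, inherits, TRUE, "fs_provider_schema")))
  if (anyDuplicated(vapply(schemas, `[[`, "", "provider_id"))) {
    fs_abort("invalid_schema", "provider ids must be unique within a schema document")
  }
  s <- character(0); p <- character(0); o <- character(0); iri <- logical(0); dt <- character(0)
  emit <- function(su, pr, ob, is_iri = FALSE, dty = NA_character_) {
    s[length(s) + 1L] <<- su; p[length(p) + 1L] <<- pr; o[length(o) + 1L] <<- ob
    iri[length(iri) + 1L] <<- is_iri; dt[length(dt) + 1L] <<- dty
  }
  lit_int <- function(su, pr, v) emit(su, pr, fmt_num(v), FALSE, paste0(XSD_NS, "integer"))
  lit_dec <- function(su, pr, v) emit(su, pr, fmt_num(v), FALSE, paste0(XSD_NS, "decimal"))
  lit_str <- function(su, pr, v) emit(su, pr, as.character(v), FALSE, NA_character_)

  for (ip in seq_along(schemas)) {
    prov <- schemas[[ip]]
    pn <- node_iri(prov$provider_id)
    emit(pn, RDF_TYPE, fs_iri("Provider"), TRUE)
    lit_str(pn, fs_iri("name"), prov$provider_id)
    lit_int(pn, fs_iri("index"), ip - 1L)
    for (is_ in seq_along(prov$sources)) {
      src <- prov$sources[[is_]]
      sn <- node_iri(prov$provider_id, src$name)
      emit(pn, fs_iri("hasSource"), sn, TRUE)
      emit(sn, RDF_TYPE, fs_iri("DataSource"), TRUE)
      lit_str(sn, fs_iri("name"), src$name)
      lit_int(sn, fs_iri("index"), is_ - 1L)
      emit(sn, fs_iri("technology"), src$technology_iri, TRUE)
      for (ie in seq_along(src$entities)) {
        ent <- src$entities[[ie]]
        en <- node_iri(prov$provider_id, src$name, ent$name)
        emit(sn, fs_iri("hasEntity"), en, TRUE)
        emit(en, RDF_TYPE, fs_iri("Entity"), TRUE)
        lit_str(en, fs_iri("name"), ent$name)
        lit_int(en, fs_iri("index"), ie - 1L)
        for (ia in seq_along(ent$attributes)) {
          at <- ent$attributes[[ia]]
          an <- node_iri(prov$provider_id, src$name, ent$name, at$name)
          emit(en, fs_iri("hasAttribute"), an, TRUE)
          emit(an, RDF_TYPE, fs_iri("Attribute"), TRUE)
          lit_str(an, fs_iri("name"), at$name)
          lit_int(an, fs_iri("index"), ia - 1L)
          emit(an, fs_iri("datatype"), at$type_iri, TRUE)
          if (!is.null(at$links_to)) {
            emit(an, fs_iri("linksTo"), node_iri(prov$provider_id, at$links_to$source, at$links_to$entity), TRUE)
          }
          pr <- at$params
          if (!is.null(pr$min)) lit_dec(an, fs_iri("genMin"), pr$min)
          if (!is.null(pr$max)) lit_dec(an, fs_iri("genMax"), pr$max)
          if (!is.null(pr$choices)) lit_str(an, fs_iri("genChoices"), paste(pr$choices, collapse = "|"))
          if (!is.null(pr$null_prob)) lit_dec(an, fs_iri("genNullProb"), pr$null_prob)
          if (!is.null(pr$length)) lit_int(an, fs_iri("genLength"), pr$length)
          if (!is.null(pr$width)) lit_int(an, fs_iri("genWidth"), pr$width)
          if (!is.null(pr$height)) lit_int(an, fs_iri("genHeight"), pr$height)
        }
      }
    }
  }
  turtle_serialize(data.frame(subject = s, predicate = p, object = o,
                              is_iri = iri, datatype = dt, stringsAsFactors = FALSE))
}

tr_objects <- function(triples, subject, predicate) {
  triples[triples$subject == subject & triples$predicate == predicate, , drop = FALSE]
}

tr_one <- function(triples, subject, predicate, what) {
  rows <- tr_objects(triples, subject, predicate)
  if (nrow(rows) != 1L) {
    fs_abort("invalid_schema", sprintf("node <%s> needs exactly one %s, found %d", subject, what, nrow(rows)))
  }
  rows$object[[1]]
}

tr_opt <- function(triples, subject, predicate) {
  rows <- tr_objects(triples, subject, predicate)
  if (nrow(rows)) rows$object[[1]] else NULL
}

tr_children <- function(triples, subject, predicate) {
  kids <- tr_objects(triples, subject, predicate)$object
  if (!length(kids)) return(character(0))
  idx <- vapply(kids, function(k) as.integer(tr_one(triples, k, fs_iri("index"), "fs:index")), 0L)
  kids[order(idx)]
}

#' Parse a Turtle schema document into provider schemas
#'
#' @param turtle_text Turtle document using the fedsmoke vocabulary.
#' @return list of [provider_schema()] objects, one per modeled provider, in
#'   declaration order.
#' @export
parse_schema_document <- function(turtle_text) {
  triples <- turtle_parse(turtle_text)
  prov_nodes <- triples$subject[triples$predicate == RDF_TYPE & triples$object == fs_iri("Provider")]
  if (!length(prov_nodes)) fs_abort("no_provider_found", "document contains no provider nodes under the fedsmoke vocabulary")
  entity_nodes <- triples$subject[triples$predicate == RDF_TYPE & triples$object == fs_iri("Entity")]
  prov_idx <- vapply(prov_nodes, function(nd) as.integer(tr_one(triples, nd, fs_iri("index"), "fs:index")), 0L)
  prov_nodes <- prov_nodes[order(prov_idx)]

  entity_name_of <- function(node) tr_one(triples, node, fs_iri("name"), "fs:name")

  parse_attr <- function(node, provider_sources) {
    params <- list()
    g <- function(pred) tr_opt(triples, node, fs_iri(pred))
    if (!is.null(g("genMin"))) params$min <- as.numeric(g("genMin"))
    if (!is.null(g("genMax"))) params$max <- as.numeric(g("genMax"))
    if (!is.null(g("genChoices"))) params$choices <- strsplit(g("genChoices"), "|", fixed = TRUE)[[1]]
    if (!is.null(g("genNullProb"))) params$null_prob <- as.numeric(g("genNullProb"))
    if (!is.null(g("genLength"))) params$length <- as.integer(g("genLength"))
    if (!is.null(g("genWidth"))) params$width <- as.integer(g("genWidth"))
    if (!is.null(g("genHeight"))) params$height <- as.integer(g("genHeight"))
    links_to <- NULL
    lt <- tr_opt(triples, node, fs_iri("linksTo"))
    if (!is.null(lt)) {
      if (!lt %in% entity_nodes) {
        fs_abort("dangling_link", sprintf("link from <%s> targets non-modeled entity <%s>", node, lt))
      }
      parts <- strsplit(sub(FS_NODE_NS, "", lt, fixed = TRUE), "/", fixed = TRUE)[[1]]
      if (length(parts) != 3L) fs_abort("invalid_schema", sprintf("unexpected entity node IRI <%s>", lt))
      links_to <- list(source = parts[2], entity = parts[3])
    }
    attribute_spec(name = tr_one(triples, node, fs_iri("name"), "fs:name"),
                   type_iri = tr_one(triples, node, fs_iri("datatype"), "fs:datatype"),
                   params = params, links_to = links_to)
  }

  lapply(prov_nodes, function(pn) {
    pid <- entity_name_of(pn)
    sources <- lapply(tr_children(triples, pn, fs_iri("hasSource")), function(sn) {
      entities <- lapply(tr_children(triples, sn, fs_iri("hasEntity")), function(en) {
        attrs <- lapply(tr_children(triples, en, fs_iri("hasAttribute")), parse_attr)
        entity_spec(entity_name_of(en), attrs)
      })
      data_source_spec(entity_name_of(sn), tr_one(triples, sn, fs_iri("technology"), "fs:technology"), entities)
    })
    schema <- provider_schema(pid, sources)
    # dangling-link detection across the provider (targets must be modeled here)
    for (src in schema$sources) for (ent in src$entities) for (at in ent$attributes) {
      if (!is.null(at$links_to)) {
        tgt <- find_entity(schema, at$links_to$source, at$links_to$entity)
        if (is.null(tgt)) {
          fs_abort("dangling_link", sprintf("attribute '%s' links to unknown entity %s/%s",
                                            at$name, at$links_to$source, at$links_to$entity))
        }
      }
    }
    schema
  })
}

find_entity <- function(schema, source_name, entity_name) {
  for (src in schema$sources) {
    if (src$name == source_name) {
      for (ent in src$entities) if (ent$name == entity_name) return(ent)
    }
  }
  NULL
}

new_diagnostic <- function(severity, path, code, message) {
  data.frame(severity = severity, path = path, code = code, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a provider schema against a plugin registry
#'
#' Checks that every source-technology IRI and attribute-type IRI resolves to
#' exactly one registered plugin of the right kind, and that every link arc
#' targets a modeled entity of the same provider. Returns diagnostics rather
#' than raising: an empty result means the schema can be provisioned.
#'
#' @param schema a [provider_schema()].
#' @param registry a [plugin_registry()].
#' @return data.frame of diagnostics with columns `severity`, `path`, `code`,
#'   `message`; zero rows iff the schema is valid.
#' @export
validate_provider_schema <- function(schema, registry) {
  stopifnot(inherits(schema, "fs_provider_schema"))
  diags <- list()
  add <- function(severity, path, code, message) diags[[length(diags) + 1L]] <<- new_diagnostic(severity, path, code, message)
  for (src in schema$sources) {
    spath <- paste(schema$provider_id, src$name, sep = "/")
    pl <- tryCatch(resolve_plugin(registry, src$technology_iri), fs_error_unresolved_iri = function(e) NULL)
    if (is.null(pl)) {
      add("error", spath, "unresolved_technology_iri",
          sprintf("technology IRI <%s> resolves to no registered Database Plugin", src$technology_iri))
    } else if (!inherits(pl, "fs_source_plugin")) {
      add("error", spath, "wrong_plugin_kind",
          sprintf("IRI <%s> is bound to a Data Plugin, not a Database Plugin", src$technology_iri))
    }
    for (ent in src$entities) {
      for (at in ent$attributes) {
        apath <- paste(spath, ent$name, at$name, sep = "/")
        dp <- tryCatch(resolve_plugin(registry, at$type_iri), fs_error_unresolved_iri = function(e) NULL)
        if (is.null(dp)) {
          add("error", apath, "unresolved_type_iri",
              sprintf("type IRI <%s> resolves to no registered Data Plugin", at$type_iri))
        } else if (!inherits(dp, "fs_data_plugin")) {
          add("error", apath, "wrong_plugin_kind",
              sprintf("IRI <%s> is bound to a Database Plugin, not a Data Plugin", at$type_iri))
        }
        if (!is.null(at$links_to) && is.null(find_entity(schema, at$links_to$source, at$links_to$entity))) {
          add("error", apath, "dangling_link",
              sprintf("link targets unknown entity %s/%s", at$links_to$source, at$links_to$entity))
        }
      }
    }
  }
  if (!length(diags)) {
    return(new_diagnostic(character(0), character(0), character(0), character(0)))
  }
  do.call(rbind, diags)
}

#' @export
print.fs_provider_schema <- function(x, ...) {
  cat(sprintf("<fs_provider_schema> %s (%d source%s)\n", x$provider_id,
              length(x$sources), if (length(x$sources) == 1) "" else "s"))
  for (src in x$sources) {
    cat(sprintf("  source %s [%s]\n", src$name, sub(FS_NS, "fs:", src$technology_iri, fixed = TRUE)))
    for (ent in src$entities) {
      cat(sprintf("    entity %s: %s\n", ent$name,
                  paste(vapply(ent$attributes, `[[`, "", "name"), collapse = ", ")))
    }
  }
  invisible(x)
}
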