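# Scenario bundles: self-contained fixtures (Turtle schema + reference
# analysis package + oracle) replicating three study settings at desk scale:
#   * user-study  -- two hospitals with mismatched relational schemas
#                    (`patients` vs `patient_info`), counting patients aged
#                    >= 50 across both;
#   * imaging     -- three providers, each a FHIR-like server (Patient,
#                    Media, ImagingStudy) interlinked with an object store
#                    of synthetic JPEGs;
#   * tabular     -- six providers with numeric feature tables and a
#                    running-statistics / pooled-mean analysis.
# The reference analyses are deterministic accumulators: the smoke-test
# criteria are agnostic to what S4 computes, so placeholder analytics
# exercise the same workflow a model-training payload would. Fault-injected
# variants plant exactly one defect each, targeting one requirement.

FAULT_KINDS <- c(WRONG_PORT = "A", BAD_CREDENTIALS = "A", SCHEMA_MISMATCH = "B",
                 CRASH = "D", MISSING_RESULT = "E", AGGREGATOR_CRASH = "F")

#' Describe an injectable fault
#' @param kind one of `WRONG_PORT`, `BAD_CREDENTIALS`, `SCHEMA_MISMATCH`,
#'   `CRASH`, `MISSING_RESULT`, `AGGREGATOR_CRASH`.
#' @param provider provider the fault is injected at (default: chosen by
#'   [inject_fault()] per kind).
#' @return an object of class `fs_fault_spec` with the targeted requirement.
#' @export
fault_spec <- function(kind, provider = NULL) {
  if (!kind %in% names(FAULT_KINDS)) {
    fs_abort("unknown_fault_kind", sprintf("unknown fault kind '%s'", kind))
  }
  structure(list(kind = kind, provider = provider,
                 targeted_requirement = unname(FAULT_KINDS[[kind]])),
            class = "fs_fault_spec")
}

write_package <- function(dir, analysis_lines, aggregator_lines, env = list()) {
  pkg <- file.path(dir, "package")
  dir.create(pkg, recursive = TRUE, showWarnings = FALSE)
  file.copy(system.file("templates", "fs_client.R", package = "fedsmoke", mustWork = TRUE),
            file.path(pkg, "fs_client.R"), overwrite = TRUE)
  writeLines(analysis_lines, file.path(pkg, "analysis.R"))
  writeLines(aggregator_lines, file.path(pkg, "aggregator.R"))
  manifest <- list(entrypoint = list("Rscript", "analysis.R"),
                   aggregator_entrypoint = list("Rscript", "aggregator.R"),
                   result_path = "state/results.json", result_format = "json")
  if (length(env)) manifest$env <- env
  yaml::write_yaml(manifest, file.path(pkg, MANIFEST_FILE))
  pkg
}

new_bundle <- function(name, dir, config, oracle, schemas) {
  writeLines(serialize_provider_schemas(schemas), file.path(dir, "schema.ttl"))
  yaml::write_yaml(list(paradigm = config$paradigm, rounds = config$rounds,
                        seed = config$seed, n_per_entity = config$n_per_entity,
                        timeout = config$timeout),
                   file.path(dir, "config.yaml"))
  structure(list(name = name, dir = dir, schema_path = file.path(dir, "schema.ttl"),
                 package_dir = file.path(dir, "package"), config = config,
                 oracle = oracle, fault = NULL, expected = NULL),
            class = "fs_scenario_bundle")
}

#' @export
print.fs_scenario_bundle <- function(x, ...) {
  cat(sprintf("<fs_scenario_bundle> %s (%s, %d round(s))%s\n", x$name, x$config$paradigm,
              x$config$rounds,
              if (!is.null(x$fault)) sprintf(" [fault %s -> Requirement %s]", x$fault$kind,
                                             x$fault$targeted_requirement) else ""))
  invisible(x)
}

#' Regenerate the synthetic datasets a bundle's simulation will see
#'
#' Uses the same per-provider seed derivation as [simulate()], so oracles
#' can be computed directly on the records the provisioned sources contain.
#'
#' @param bundle an `fs_scenario_bundle`.
#' @param registry plugin registry.
#' @return named list provider_id -> `fs_dataset`.
#' @export
scenario_datasets <- function(bundle, registry = default_registry()) {
  schemas <- parse_schema_document(readLines(bundle$schema_path))
  out <- lapply(schemas, function(s) {
    generate_dataset(s, bundle$config$n_per_entity, derive_seed(bundle$config$seed, s$provider_id), registry)
  })
  names(out) <- vapply(schemas, `[[`, "", "provider_id")
  out
}

#' Run a scenario bundle end to end
#' @param bundle an `fs_scenario_bundle`.
#' @param registry plugin registry.
#' @return list with the `trace`, the smoke-test `report` and the parsed
#'   final `result` artifact.
#' @export
run_scenario <- function(bundle, registry = default_registry()) {
  schemas <- parse_schema_document(readLines(bundle$schema_path))
  package <- load_package(bundle$package_dir)
  trace <- simulate(bundle$config, schemas, package, registry)
  report <- evaluate_trace(trace)
  list(trace = trace, report = report, result = trace$final_result$parsed)
}

user_study_schemas <- function() {
  hospital_a <- provider_schema("hospital_a", list(
    data_source_spec("hospitaldb", fs_iri("relational"), list(
      entity_spec("patients", list(
        attribute_spec("patient_id", fs_iri("uuid")),
        attribute_spec("age", fs_iri("integer"), list(min = 0, max = 100)),
        attribute_spec("treatment", fs_iri("categorical"),
                       list(choices = c("chemotherapy", "surgery", "radiation", "none"))),
        attribute_spec("last_treatment", fs_iri("date"))))))))
  hospital_b <- provider_schema("hospital_b", list(
    data_source_spec("hospitaldb", fs_iri("relational"), list(
      entity_spec("patient_info", list(
        attribute_spec("patient_id", fs_iri("uuid")),
        attribute_spec("age", fs_iri("integer"), list(min = 0, max = 100)),
        attribute_spec("insurance_provider", fs_iri("categorical"),
                       list(choices = c("aok", "tk", "barmer", "dak"))),
        attribute_spec("insurance_id", fs_iri("string"), list(length = 10))))))))
  list(hospital_a, hospital_b)
}

user_study_analysis <- c(
  '# Count patients aged >= 50 at this provider; under IIL the count',
  '# accumulates across hops, under FL each replica reports its local count.',
  'source("fs_client.R")',
  'res_path <- Sys.getenv("RESULT_PATH", "state/results.json")',
  'paradigm <- Sys.getenv("FS_PARADIGM", "IIL")',
  'pid <- Sys.getenv("FS_PROVIDER_ID")',
  'fault <- Sys.getenv("FS_FAULT", "")',
  'fault_here <- fault != "" && Sys.getenv("FS_FAULT_PROVIDER", pid) == pid',
  '',
  'src <- fs_source("hospitaldb")',
  'if (!fs_connect(src)) { message("cannot connect to hospitaldb"); quit(save = "no", status = 1) }',
  '',
  '# the relation name differs between hospitals; FS_TABLE overrides the',
  '# per-provider mapping (the naive single-table variant sets it)',
  'tbl <- Sys.getenv("FS_TABLE", "")',
  'if (tbl == "") tbl <- if (identical(pid, "hospital_a")) "patients" else "patient_info"',
  'resp <- fs_query_sql(src, sprintf("SELECT COUNT(*) FROM %s WHERE age >= 50", tbl))',
  'if (!isTRUE(resp$ok)) { message("query failed: ", resp$detail); quit(save = "no", status = 1) }',
  'n50 <- as.numeric(fs_agg_value(resp))',
  '',
  'if (fault_here && fault == "CRASH") stop("injected fault: crash during analysis")',
  '',
  'prev <- fs_read_json(res_path)',
  'count <- if (identical(paradigm, "IIL")) {',
  '  (if (is.null(prev)) 0 else as.numeric(prev$count)) + n50',
  '} else n50',
  'if (!(fault_here && fault == "MISSING_RESULT")) {',
  '  fs_write_json(list(count = count, provider = pid), res_path)',
  '}')

sum_aggregator <- function(fields) c(
  '# Combine replica results into the round global result.',
  'library(jsonlite)',
  'if (Sys.getenv("FS_FAULT", "") == "AGGREGATOR_CRASH") stop("injected fault: aggregator crash")',
  'ind <- Sys.getenv("AGGREGATION_INPUT_DIR")',
  'files <- list.files(ind, pattern = "\\\\.json$", recursive = TRUE, full.names = TRUE)',
  'inputs <- lapply(files, function(f) fromJSON(f, simplifyVector = FALSE))',
  sprintf('fields <- c(%s)', paste(sprintf('"%s"', fields), collapse = ", ")),
  'out <- lapply(fields, function(f) sum(vapply(inputs, function(x) as.numeric(x[[f]]), 0)))',
  'names(out) <- fields',
  'out$n_inputs <- length(inputs)',
  'if ("sum_a" %in% fields && "n" %in% fields && out$n > 0) out$mean_a <- out$sum_a / out$n',
  'path <- Sys.getenv("RESULT_PATH", "state/results.json")',
  'if (!dir.exists(dirname(path))) dir.create(dirname(path), recursive = TRUE)',
  'write_json(out, path, auto_unbox = TRUE, digits = NA)')

#' Build the two-hospital user-study scenario
#'
#' Hospital A models its patient relation as `patients`, Hospital B as
#' `patient_info`, with differing extra attributes (treatment history vs
#' insurance columns) -- deliberate schema heterogeneity. The reference
#' analysis maps the relation name per provider and accumulates the number
#' of patients aged at least 50; the oracle counts the same predicate
#' directly over the generated records.
#'
#' @param seed root seed.
#' @param n_per_provider synthetic patients per hospital.
#' @param paradigm execution paradigm for the bundle config.
#' @param rounds rounds to simulate.
#' @param dir bundle directory (default: a temp dir).
#' @return an `fs_scenario_bundle`.
#' @export
make_user_study_scenario <- function(seed = 1L, n_per_provider = 50L, paradigm = "IIL",
                                     rounds = 1L, dir = tempfile("fs-user-study-")) {
  stopifnot(is_count(n_per_provider))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- simulation_config(paradigm = paradigm, rounds = rounds, seed = seed,
                              n_per_entity = n_per_provider,
                              order = c("hospital_a", "hospital_b"))
  write_package(dir, user_study_analysis, sum_aggregator("count"))
  oracle <- function(datasets) {
    sum(vapply(datasets, function(d) {
      recs <- d$records$hospitaldb[[1]]
      sum(vapply(recs, function(r) isTRUE(r$age >= 50), TRUE))
    }, 0))
  }
  new_bundle("user_study", dir, config, oracle, user_study_schemas())
}

imaging_schemas <- function(n_providers) {
  lapply(seq_len(n_providers), function(i) {
    provider_schema(sprintf("clinic_%d", i), list(
      data_source_spec("imagestore", fs_iri("objectstore"), list(
        entity_spec("images", list(
          attribute_spec("content", fs_iri("jpeg"), list(width = 64, height = 64)))))),
      data_source_spec("fhirstore", fs_iri("fhir"), list(
        entity_spec("Patient", list(
          attribute_spec("resource", fs_iri("fhir-Patient")))),
        entity_spec("Media", list(
          attribute_spec("resource", fs_iri("fhir-Media")),
          attribute_spec("patient", fs_iri("uuid"),
                         links_to = list(source = "fhirstore", entity = "Patient")),
          attribute_spec("image", fs_iri("uuid"),
                         links_to = list(source = "imagestore", entity = "images")))),
        entity_spec("ImagingStudy", list(
          attribute_spec("resource", fs_iri("fhir-ImagingStudy")),
          attribute_spec("patient", fs_iri("uuid"),
                         links_to = list(source = "fhirstore", entity = "Patient"))))))))
  })
}

imaging_analysis <- c(
  '# Fetch Media resources from the FHIR-like source and read every',
  '# referenced image blob from the object store (stand-in for the image',
  '# pipeline of a classifier): records counts and byte totals.',
  'source("fs_client.R")',
  'res_path <- Sys.getenv("RESULT_PATH", "state/results.json")',
  'paradigm <- Sys.getenv("FS_PARADIGM", "IIL")',
  'pid <- Sys.getenv("FS_PROVIDER_ID")',
  'fault <- Sys.getenv("FS_FAULT", "")',
  'fault_here <- fault != "" && Sys.getenv("FS_FAULT_PROVIDER", pid) == pid',
  '',
  'fhir <- fs_source("fhirstore")',
  'store <- fs_source("imagestore")',
  'if (!fs_connect(fhir) || !fs_connect(store)) { message("cannot connect"); quit(save = "no", status = 1) }',
  '',
  'media <- fs_fhir_list(fhir, "Media")',
  'if (!isTRUE(media$ok)) { message("query failed: ", media$detail); quit(save = "no", status = 1) }',
  'n_media <- length(media$resources)',
  'n_resolved <- 0; n_bytes <- 0',
  'for (m in media$resources) {',
  '  key <- sub("^objects/", "", m$content$url)',
  '  r <- fs_get_object(store, key)',
  '  if (isTRUE(r$ok)) { n_resolved <- n_resolved + 1; n_bytes <- n_bytes + r$size }',
  '}',
  '',
  'if (fault_here && fault == "CRASH") stop("injected fault: crash during analysis")',
  '',
  'prev <- if (identical(paradigm, "IIL")) fs_read_json(res_path) else NULL',
  'acc <- function(f, v) (if (is.null(prev)) 0 else as.numeric(prev[[f]])) + v',
  'out <- list(n_media = acc("n_media", n_media), n_resolved = acc("n_resolved", n_resolved),',
  '            n_bytes = acc("n_bytes", n_bytes))',
  'if (!(fault_here && fault == "MISSING_RESULT")) fs_write_json(out, res_path)')

#' Build the imaging scenario (FHIR-like server + object store per provider)
#'
#' Each provider offers two interlinked sources: a FHIR-like endpoint
#' serving Patient, Media and ImagingStudy resources, and an object store
#' of synthetic 64x64 JPEGs. Every Media resource references a Patient and
#' an image blob. Defaults: 3 providers, 10 instances per entity.
#'
#' @param seed root seed.
#' @param n_providers number of providers.
#' @param n_per_source synthetic instances per entity.
#' @param paradigm execution paradigm.
#' @param rounds rounds to simulate.
#' @param dir bundle directory.
#' @return an `fs_scenario_bundle`.
#' @export
make_imaging_scenario <- function(seed = 1L, n_providers = 3L, n_per_source = 10L,
                                  paradigm = "IIL", rounds = 1L, dir = tempfile("fs-imaging-")) {
  stopifnot(is_count(n_providers), is_count(n_per_source))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schemas <- imaging_schemas(n_providers)
  config <- simulation_config(paradigm = paradigm, rounds = rounds, seed = seed,
                              n_per_entity = n_per_source,
                              order = vapply(schemas, `[[`, "", "provider_id"))
  write_package(dir, imaging_analysis, sum_aggregator(c("n_media", "n_resolved", "n_bytes")))
  oracle <- function(datasets) {
    n_media <- sum(vapply(datasets, function(d) length(d$records$fhirstore$Media), 0L))
    resolved <- sum(vapply(datasets, function(d) {
      sum(vapply(d$records$fhirstore$Media, function(m) {
        key <- sub("^objects/", "", m$resource$content$url)
        as.integer(key %in% names(d$blobs))
      }, 0L))
    }, 0L))
    list(n_media = n_media, n_resolved = resolved)
  }
  new_bundle("imaging", dir, config, oracle, schemas)
}

tabular_schemas <- function(n_providers) {
  lapply(seq_len(n_providers), function(i) {
    provider_schema(sprintf("site_%d", i), list(
      data_source_spec("csvstore", fs_iri("relational"), list(
        entity_spec("measurements", list(
          attribute_spec("sample_id", fs_iri("uuid")),
          attribute_spec("feature_a", fs_iri("double"), list(min = 0, max = 10)),
          attribute_spec("feature_b", fs_iri("double"), list(min = 0, max = 1)),
          attribute_spec("label", fs_iri("integer"), list(min = 0, max = 1))))))))
  })
}

tabular_analysis <- c(
  '# Running-statistics accumulator over the numeric feature table',
  '# (stand-in for a distributed regression fit): tracks n and sum of',
  '# feature_a; the mean is recomputed from the accumulated sums.',
  'source("fs_client.R")',
  'res_path <- Sys.getenv("RESULT_PATH", "state/results.json")',
  'paradigm <- Sys.getenv("FS_PARADIGM", "IIL")',
  'pid <- Sys.getenv("FS_PROVIDER_ID")',
  'fault <- Sys.getenv("FS_FAULT", "")',
  'fault_here <- fault != "" && Sys.getenv("FS_FAULT_PROVIDER", pid) == pid',
  '',
  'src <- fs_source("csvstore")',
  'if (!fs_connect(src)) { message("cannot connect"); quit(save = "no", status = 1) }',
  'n_resp <- fs_query_sql(src, "SELECT COUNT(*) FROM measurements")',
  's_resp <- fs_query_sql(src, "SELECT SUM(feature_a) FROM measurements")',
  'if (!isTRUE(n_resp$ok) || !isTRUE(s_resp$ok)) { message("query failed"); quit(save = "no", status = 1) }',
  'n <- as.numeric(fs_agg_value(n_resp)); s <- as.numeric(fs_agg_value(s_resp))',
  '',
  'if (fault_here && fault == "CRASH") stop("injected fault: crash during analysis")',
  '',
  'prev <- if (identical(paradigm, "IIL")) fs_read_json(res_path) else NULL',
  'n_tot <- (if (is.null(prev)) 0 else as.numeric(prev$n)) + n',
  's_tot <- (if (is.null(prev)) 0 else as.numeric(prev$sum_a)) + s',
  'out <- list(n = n_tot, sum_a = s_tot, mean_a = s_tot / n_tot)',
  'if (!(fault_here && fault == "MISSING_RESULT")) fs_write_json(out, res_path)')

#' Build the tabular multi-site scenario
#'
#' Six providers (by default) each offer a relational source with numeric
#' feature columns and a binary label. The IIL analysis accumulates running
#' statistics across sites; under FL the aggregator pools per-site sums, so
#' the global feature mean equals the pooled mean over all generated rows.
#'
#' @param seed root seed.
#' @param n_providers number of providers.
#' @param n_rows rows per provider.
#' @param paradigm execution paradigm.
#' @param rounds rounds to simulate.
#' @param dir bundle directory.
#' @return an `fs_scenario_bundle`.
#' @export
make_tabular_scenario <- function(seed = 1L, n_providers = 6L, n_rows = 90L,
                                  paradigm = "IIL", rounds = 1L, dir = tempfile("fs-tabular-")) {
  stopifnot(is_count(n_providers), is_count(n_rows))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schemas <- tabular_schemas(n_providers)
  config <- simulation_config(paradigm = paradigm, rounds = rounds, seed = seed,
                              n_per_entity = n_rows,
                              order = vapply(schemas, `[[`, "", "provider_id"))
  write_package(dir, tabular_analysis, sum_aggregator(c("n", "sum_a")))
  oracle <- function(datasets) {
    vals <- unlist(lapply(datasets, function(d) {
      vapply(d$records$csvstore$measurements, `[[`, 0, "feature_a")
    }))
    list(n = length(vals), sum_a = sum(vals), mean_a = mean(vals))
  }
  new_bundle("tabular", dir, config, oracle, schemas)
}

#' Inject a canonical fault into a scenario bundle
#'
#' Returns a modified copy of the bundle expected to FAIL exactly the
#' fault's targeted requirement at the injection site. Connection faults
#' (`WRONG_PORT`, `BAD_CREDENTIALS`) corrupt the injected connection
#' variables of one provider; `SCHEMA_MISMATCH` switches the user-study
#' analysis to the naive single-table query; `CRASH`, `MISSING_RESULT` and
#' `AGGREGATOR_CRASH` arm fault hooks in the reference analysis scripts.
#'
#' @param bundle an `fs_scenario_bundle`.
#' @param fault an [fault_spec()] (or a fault-kind string).
#' @return a new `fs_scenario_bundle` with `fault` and `expected` metadata.
#' @export
inject_fault <- function(bundle, fault) {
  if (is.character(fault)) fault <- fault_spec(fault)
  stopifnot(inherits(bundle, "fs_scenario_bundle"), inherits(fault, "fs_fault_spec"))
  if (fault$kind == "AGGREGATOR_CRASH" && bundle$config$paradigm == "IIL") {
    fs_abort("fault_not_applicable", "AGGREGATOR_CRASH needs an aggregation paradigm (FL or FL_INC)")
  }
  if (fault$kind == "SCHEMA_MISMATCH" && bundle$name != "user_study") {
    fs_abort("fault_not_applicable", "SCHEMA_MISMATCH is defined for the user-study bundle")
  }
  new_dir <- tempfile(sprintf("fs-fault-%s-", tolower(fault$kind)))
  dir.create(new_dir, recursive = TRUE)
  copy_tree(bundle$dir, new_dir)
  out <- bundle
  out$dir <- new_dir
  out$schema_path <- file.path(new_dir, "schema.ttl")
  out$package_dir <- file.path(new_dir, "package")
  site <- fault$provider %||% switch(fault$kind,
    SCHEMA_MISMATCH = "hospital_b",
    AGGREGATOR_CRASH = AGGREGATOR_ID,
    bundle$config$order[1])

  mpath <- file.path(out$package_dir, MANIFEST_FILE)
  manifest <- yaml::read_yaml(mpath)
  if (fault$kind %in% c("WRONG_PORT", "BAD_CREDENTIALS")) {
    cf <- out$config$connection_faults
    cf[[site]] <- fault$kind
    out$config$connection_faults <- cf
  } else if (fault$kind == "SCHEMA_MISMATCH") {
    manifest$env <- c(manifest$env %||% list(), list(FS_TABLE = "patients"))
  } else if (fault$kind == "AGGREGATOR_CRASH") {
    manifest$env <- c(manifest$env %||% list(), list(FS_FAULT = "AGGREGATOR_CRASH"))
  } else {
    manifest$env <- c(manifest$env %||% list(),
                      list(FS_FAULT = fault$kind, FS_FAULT_PROVIDER = site))
  }
  yaml::write_yaml(manifest, mpath)
  fault$provider <- site
  out$fault <- fault
  out$expected <- list(requirement = fault$targeted_requirement, provider = site)
  out
}

#' Emit a runnable scenario bundle to a directory
#'
#' Convenience wrapper used by the command-line interface: builds one of
#' the named scenarios with its default configuration into `out_dir`.
#'
#' @param name `"user_study"`, `"imaging"` or `"tabular"`.
#' @param out_dir target directory.
#' @param seed root seed.
#' @param paradigm execution paradigm recorded in the bundle config.
#' @return the `fs_scenario_bundle`, invisibly.
#' @export
emit_scenario <- function(name, out_dir, seed = 1L, paradigm = "IIL") {
  bundle <- switch(name,
    user_study = make_user_study_scenario(seed = seed, paradigm = paradigm, dir = out_dir),
    imaging = make_imaging_scenario(seed = seed, paradigm = paradigm, dir = out_dir),
    tabular = make_tabular_scenario(seed = seed, paradigm = paradigm, dir = out_dir),
    fs_abort("config_invalid", sprintf("unknown scenario '%s'", name)))
  invisible(bundle)
}
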