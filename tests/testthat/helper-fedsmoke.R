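# Shared fixtures: all schemas, datasets and analysis packages are built in
# code at test time.

reg_default <- default_registry()

tiny_schema <- function(pid = "alpha") {
  provider_schema(pid, list(
    data_source_spec("db", fs_iri("relational"), list(
      entity_spec("items", list(
        attribute_spec("item_id", fs_iri("uuid")),
        attribute_spec("score", fs_iri("integer"), list(min = 0, max = 9)),
        attribute_spec("grp", fs_iri("categorical"), list(choices = c("x", "y")))))))))
}

# a small random schema generator for property-style round-trip checks
random_schema <- function(stream, pid) {
  types <- c("integer", "double", "string", "boolean", "date", "categorical", "uuid")
  n_src <- rs_int(stream, 1L, 2L)
  sources <- lapply(seq_len(n_src), function(si) {
    n_ent <- rs_int(stream, 1L, 2L)
    entities <- lapply(seq_len(n_ent), function(ei) {
      n_at <- rs_int(stream, 1L, 4L)
      attrs <- lapply(seq_len(n_at), function(ai) {
        ty <- rs_pick(stream, types)
        params <- switch(ty,
          integer = list(min = rs_int(stream, 0L, 5L), max = rs_int(stream, 6L, 99L)),
          double = list(min = 0, max = rs_int(stream, 1L, 10L)),
          categorical = list(choices = c("red", "green", "blue")),
          string = list(length = rs_int(stream, 4L, 16L)),
          list())
        attribute_spec(sprintf("attr_%d", ai), fs_iri(ty), params)
      })
      entity_spec(sprintf("ent_%d", ei), attrs)
    })
    data_source_spec(sprintf("src_%d", si), fs_iri("relational"), entities)
  })
  provider_schema(pid, sources)
}

fixture_package <- function(analysis, aggregator = NULL, env = list(),
                            result_path = "state/results.json", dir = tempfile("fixpkg-")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(system.file("templates", "fs_client.R", package = "fedsmoke", mustWork = TRUE),
            file.path(dir, "fs_client.R"))
  writeLines(analysis, file.path(dir, "analysis.R"))
  manifest <- list(entrypoint = list("Rscript", "analysis.R"),
                   result_path = result_path, result_format = "json")
  if (!is.null(aggregator)) {
    writeLines(aggregator, file.path(dir, "aggregator.R"))
    manifest$aggregator_entrypoint <- list("Rscript", "aggregator.R")
  }
  if (length(env)) manifest$env <- env
  yaml::write_yaml(manifest, file.path(dir, "fedsmoke.yaml"))
  load_package(dir)
}

# provision a provider and register teardown with the calling test
provisioned <- function(schema, n = 10, seed = 1, env = parent.frame()) {
  ds <- generate_dataset(schema, n, seed, reg_default)
  hs <- provision_provider(schema, ds, reg_default, base_dir = tempfile())
  withr::defer(teardown_provider(hs), envir = env)
  list(handles = hs, dataset = ds)
}

fake_outcome <- function(exit = 0L, result_status = "ok", stderr = "", timed_out = FALSE) {
  structure(list(exit_code = as.integer(exit), timed_out = timed_out, stdout = "",
                 stderr = stderr,
                 result = list(status = result_status, path = "state/results.json"),
                 client_events = list()),
            class = "fs_run_outcome")
}

fake_telemetry <- function(kinds, error_classes = NA_character_) {
  data.frame(ts = rep("", length(kinds)), source = rep("db", length(kinds)), kind = kinds,
             error_class = rep_len(error_classes, length(kinds)),
             detail = rep("", length(kinds)), stringsAsFactors = FALSE)
}

expect_fs_error <- function(expr, subclass) {
  expect_error(expr, class = paste0("fs_error_", subclass))
}
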