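# Source fabric: provisions isolated, queryable simulated data sources from
# (schema, dataset) pairs. Every source gets its own background gateway
# process on its own loopback port; every provider gets its own credentials.
# The connection surface handed to analysis code is a set of environment
# variables (<SOURCE>_HOST/_PORT/_USER/_PASSWORD/_TYPE), mirroring how a
# simulation engine injects credentials into an analysis container.

FS_PORT_BASE <- 20000L
FS_PORT_RANGE <- 20000L

port_is_free <- function(port) {
  s <- tryCatch(serverSocket(port), error = function(e) NULL)
  if (is.null(s)) return(FALSE)
  close(s)
  TRUE
}

env_prefix <- function(source_name) toupper(gsub("[^A-Za-z0-9]", "_", source_name))

new_source_handle <- function(fields) {
  h <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = h)
  class(h) <- "fs_source_handle"
  h
}

#' @export
print.fs_source_handle <- function(x, ...) {
  cat(sprintf("<fs_source_handle> %s/%s [%s] %s:%s %s\n", x$provider_id, x$source_name,
              x$type, x$host, x$port, if (x$live) "live" else "down"))
  invisible(x)
}

#' Provision all data sources of one provider
#'
#' Starts one background gateway server per source, inserts the synthetic
#' dataset, and returns handles carrying the connection credentials. Sources
#' of the same provider share one user/password pair; different providers
#' never share credentials or ports.
#'
#' @param schema the [provider_schema()] the dataset was generated from.
#' @param dataset the matching [generate_dataset()] result.
#' @param registry a [plugin_registry()] resolving each technology IRI.
#' @param base_dir directory for spool state (default: a session temp dir).
#' @param host loopback address served on.
#' @return list of `fs_source_handle`, one per source, with empty telemetry.
#' @export
provision_provider <- function(schema, dataset, registry, base_dir = NULL, host = "127.0.0.1") {
  stopifnot(inherits(schema, "fs_provider_schema"), inherits(dataset, "fs_dataset"))
  if (!identical(schema$provider_id, dataset$provider_id)) {
    fs_abort("invalid_params", "dataset was generated for a different provider")
  }
  base_dir <- base_dir %||% file.path(tempdir(), "fedsmoke-fabric")
  cred_stream <- random_stream(derive_seed(dataset$seed, schema$provider_id, "credentials"))
  user <- sprintf("user_%s", schema$provider_id)
  password <- rs_hex(cred_stream, 24)

  handles <- list()
  for (src in schema$sources) {
    plugin <- resolve_plugin(registry, src$technology_iri)
    if (!inherits(plugin, "fs_source_plugin")) {
      fs_abort("unresolved_iri", sprintf("IRI <%s> is not bound to a Database Plugin", src$technology_iri))
    }
    spool <- file.path(base_dir, schema$provider_id, src$name)
    unlink(spool, recursive = TRUE)
    dir.create(file.path(spool, "data"), recursive = TRUE, showWarnings = FALSE)

    for (ent in src$entities) {
      recs <- dataset$records[[src$name]][[ent$name]] %||% list()
      writeLines(canonical_json(recs), file.path(spool, "data", paste0(ent$name, ".json")))
    }
    src_blob_prefix <- paste0(src$name, "/")
    for (key in names(dataset$blobs)) {
      if (startsWith(key, src_blob_prefix)) {
        path <- file.path(spool, "blobs", key)
        dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
        writeBin(dataset$blobs[[key]], path)
      }
    }
    file.create(file.path(spool, "telemetry.ndjson"))

    port_stream <- random_stream(derive_seed(dataset$seed, schema$provider_id, src$name, "port"))
    port <- NA_integer_
    for (attempt in seq_len(32)) {
      cand <- FS_PORT_BASE + ((rs_int(port_stream, 0L, FS_PORT_RANGE - 1L) + (attempt - 1L) * 977L) %% FS_PORT_RANGE)
      if (!port_is_free(cand)) next
      cfg <- list(source_name = src$name, provider_id = schema$provider_id,
                  port = cand, type = plugin$backend, user = user, password = password)
      writeLines(canonical_json(cfg), file.path(spool, "config.json"))
      unlink(file.path(spool, "ready"))
      rscript <- file.path(R.home("bin"), "Rscript")
      cmd <- sprintf("R_LIBS=%s %s -e 'fedsmoke::run_source_server()' %s > %s 2>&1",
                     shQuote(paste(.libPaths(), collapse = ":")), shQuote(rscript),
                     shQuote(spool), shQuote(file.path(spool, "server.log")))
      system(cmd, wait = FALSE)
      ready <- NULL
      ok <- wait_until(function() {
        f <- file.path(spool, "ready")
        if (!file.exists(f)) return(FALSE)
        l <- tryCatch(readLines(f, warn = FALSE), error = function(e) character(0))
        if (!length(l) || is.na(l[1]) || !nzchar(l[1])) return(FALSE)
        ready <<- l[1]
        TRUE
      }, timeout = 20)
      if (ok && startsWith(ready %||% "", "ok:")) { port <- cand; break }
    }
    if (is.na(port)) fs_abort("port_unavailable", sprintf("could not provision source %s on any port", src$name))

    handles[[src$name]] <- new_source_handle(list(
      spec = src, source_name = src$name, provider_id = schema$provider_id,
      type = plugin$backend, host = host, port = port, user = user, password = password,
      spool = spool, telemetry_file = file.path(spool, "telemetry.ndjson"),
      pid = as.integer(readLines(file.path(spool, "pid"), warn = FALSE)[1]),
      live = TRUE, external = FALSE))
  }
  handles
}

#' Connection environment variables for one source handle
#' @param handle an `fs_source_handle`.
#' @return named character vector of `<SOURCE>_HOST/_PORT/_USER/_PASSWORD/_TYPE/_PATH`.
#' @export
connection_info <- function(handle) {
  stopifnot(inherits(handle, "fs_source_handle"))
  pre <- env_prefix(handle$source_name)
  vars <- c(HOST = handle$host, PORT = as.character(handle$port),
            USER = handle$user %||% "", PASSWORD = handle$password %||% "",
            TYPE = handle$type, PATH = handle$spool %||% "")
  stats::setNames(unname(vars), paste0(pre, "_", names(vars)))
}

#' Connection environment for all sources of one provider
#' @param handles list of `fs_source_handle` from [provision_provider()].
#' @return named character vector including `FS_PROVIDER_ID`.
#' @export
provider_conn_env <- function(handles) {
  env <- do.call(c, unname(lapply(handles, connection_info)))
  c(env, FS_PROVIDER_ID = handles[[1]]$provider_id)
}

#' Query a provisioned source through its gateway
#'
#' Sends one request over the source's loopback gateway. Authentication is
#' checked server-side before execution; the outcome is appended to the
#' source's telemetry (a connection that never reaches the server is
#' recorded client-side as `CONNECT_FAIL`). Structured errors are returned,
#' never raised.
#'
#' @param handle an `fs_source_handle`.
#' @param credentials optional `list(user =, password =)`; defaults to the
#'   handle's own credentials.
#' @param request named list with `op` plus op arguments, e.g.
#'   `list(op = "query", sql = "SELECT COUNT(*) FROM patients")`,
#'   `list(op = "fhir_list", type = "Patient")`, `list(op = "object_get", key = k)`.
#' @param timeout seconds to wait for the gateway.
#' @return response list: `ok = TRUE` with results, or `ok = FALSE` with
#'   `error_class` and `detail`.
#' @export
gateway_query <- function(handle, credentials = NULL, request = list(op = "ping"), timeout = 10) {
  stopifnot(inherits(handle, "fs_source_handle"))
  credentials <- credentials %||% list(user = handle$user, password = handle$password)
  payload <- c(request, list(user = credentials$user %||% "", password = credentials$password %||% ""))
  gateway_request(handle$host, handle$port, payload, timeout = timeout,
                  telemetry_file = handle$telemetry_file, source_name = handle$source_name)
}

#' Read a source's telemetry log
#' @param handle an `fs_source_handle`.
#' @return data.frame of events (`ts`, `source`, `kind`, `error_class`, `detail`).
#' @export
source_telemetry <- function(handle) {
  events <- read_ndjson(handle$telemetry_file)
  if (!length(events)) {
    return(data.frame(ts = character(0), source = character(0), kind = character(0),
                      error_class = character(0), detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(events, function(e) {
    data.frame(ts = e$ts %||% "", source = e$source %||% "", kind = e$kind %||% "",
               error_class = e$error_class %||% NA_character_, detail = e$detail %||% "",
               stringsAsFactors = FALSE)
  }))
}

#' Attach an already-running external data source
#'
#' Wraps an existing endpoint in a source handle whose gateway client
#' forwards requests verbatim. No dataset is generated or inserted; server
#' internals are not introspected, so step evidence from such a source is
#' classified conservatively (`UNOBSERVED` unless a failure is recorded).
#'
#' @param name source name used for the connection-variable prefix.
#' @param endpoint `list(host =, port =, user =, password =)`.
#' @param provider_id provider the source is attributed to.
#' @return an `fs_source_handle` with `external = TRUE`.
#' @export
attach_external_source <- function(name, endpoint, provider_id = "external") {
  stopifnot(is_string(name))
  con <- tryCatch(
    suppressWarnings(socketConnection(endpoint$host, as.integer(endpoint$port), open = "r+",
                                      blocking = TRUE, timeout = 3)),
    error = function(e) NULL)
  if (is.null(con)) {
    fs_abort("endpoint_unreachable", sprintf("endpoint %s:%s is not reachable", endpoint$host, endpoint$port))
  }
  close(con)
  new_source_handle(list(
    spec = NULL, source_name = name, provider_id = provider_id, type = "external",
    host = endpoint$host, port = as.integer(endpoint$port),
    user = endpoint$user %||% "", password = endpoint$password %||% "",
    spool = NULL, telemetry_file = tempfile(fileext = ".ndjson"),
    pid = NA_integer_, live = TRUE, external = TRUE))
}

#' Tear down provisioned sources
#'
#' Stops the background gateway processes and releases their ports.
#' Telemetry logs are retained for reporting. Idempotent; external handles
#' are only marked down.
#'
#' @param handles list of `fs_source_handle` (or a single handle).
#' @return invisibly, `NULL`.
#' @export
teardown_provider <- function(handles) {
  if (inherits(handles, "fs_source_handle")) handles <- list(handles)
  for (h in handles) {
    if (isTRUE(h$live) && !isTRUE(h$external) && !is.na(h$pid)) {
      tools::pskill(h$pid)
      wait_until(function() port_is_free(h$port), timeout = 5)
    }
    h$live <- FALSE
  }
  invisible(NULL)
}
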