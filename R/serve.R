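# Loopback gateway server for one provisioned data source.
#
# Each source runs in its own background R process, listening on its own
# loopback port. The wire protocol is one JSON object per line in each
# direction: the request carries `op`, credentials and op arguments, the
# response `ok` plus either the result or `error_class`/`detail`. The
# server authenticates before executing, never crashes on a bad request,
# and appends exactly one telemetry event per request to the source's
# telemetry log.

TELEMETRY_KINDS <- c("CONNECT_OK", "CONNECT_FAIL", "AUTH_FAIL", "QUERY_OK", "QUERY_FAIL")
ERROR_CLASSES <- c("UNKNOWN_RELATION", "UNKNOWN_ATTRIBUTE", "SYNTAX", "TYPE_MISMATCH", "NOT_FOUND", "OTHER")

telemetry_event <- function(source, kind, error_class = NA_character_, detail = "") {
  list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), source = source, kind = kind,
       error_class = error_class, detail = detail)
}

gw_ok <- function(...) c(list(ok = TRUE), list(...))
gw_err <- function(error_class, detail) list(ok = FALSE, error_class = error_class, detail = detail)

# Dispatch one parsed request against the in-memory store. Returns
# list(response=, event_kind=, error_class=, detail=).
gw_handle <- function(req, store) {
  cfg <- store$config
  op <- req$op %||% ""
  if (op == "ping") {
    return(list(response = gw_ok(source = cfg$source_name, type = cfg$type),
                event = "CONNECT_OK", detail = "ping"))
  }
  fail <- function(error_class, detail) {
    list(response = gw_err(error_class, detail), event = "QUERY_FAIL",
         error_class = error_class, detail = detail)
  }
  done <- function(response, detail) list(response = response, event = "QUERY_OK", detail = detail)

  if (op == "query") {
    if (cfg$type != "relational") return(fail("OTHER", sprintf("SQL not supported by %s source", cfg$type)))
    if (!is_string(req$sql %||% "")) return(fail("SYNTAX", "missing sql text"))
    res <- sql_execute(req$sql, store$tables)
    if (isTRUE(res$ok)) return(done(res, sprintf("sql: %s", req$sql)))
    return(fail(res$error_class, res$detail))
  }
  if (op == "docquery") {
    if (cfg$type != "document") return(fail("OTHER", sprintf("document filter not supported by %s source", cfg$type)))
    ent <- req$entity %||% ""
    if (!ent %in% names(store$tables)) return(fail("UNKNOWN_RELATION", sprintf("collection \"%s\" does not exist", ent)))
    recs <- store$tables[[ent]]
    flt <- req$filter
    if (length(flt)) {
      known <- unique(unlist(lapply(recs, names)))
      for (k in names(flt)) {
        if (!k %in% known) return(fail("UNKNOWN_ATTRIBUTE", sprintf("field \"%s\" does not exist in \"%s\"", k, ent)))
      }
      recs <- Filter(function(r) all(vapply(names(flt), function(k) identical(r[[k]], flt[[k]]), TRUE)), recs)
    }
    return(done(gw_ok(records = recs), sprintf("docquery %s", ent)))
  }
  if (op == "fhir_meta") {
    if (cfg$type != "fhir") return(fail("OTHER", "not a FHIR-like source"))
    return(done(gw_ok(resourceTypes = as.list(names(store$tables))), "fhir metadata"))
  }
  if (op %in% c("fhir_list", "fhir_get")) {
    if (cfg$type != "fhir") return(fail("OTHER", "not a FHIR-like source"))
    type <- req$type %||% ""
    if (!type %in% names(store$tables)) {
      return(fail("UNKNOWN_RELATION", sprintf("resource type \"%s\" is not served here", type)))
    }
    resources <- lapply(store$tables[[type]], extract_resource)
    if (op == "fhir_list") return(done(gw_ok(resources = resources), sprintf("fhir list %s", type)))
    ids <- vapply(resources, function(r) r$id %||% "", "")
    hit <- which(ids == (req$id %||% ""))
    if (!length(hit)) return(fail("NOT_FOUND", sprintf("%s/%s not found", type, req$id %||% "")))
    return(done(gw_ok(resource = resources[[hit[1]]]), sprintf("fhir get %s/%s", type, req$id)))
  }
  if (op == "object_get") {
    if (cfg$type != "objectstore") return(fail("OTHER", "not an object store"))
    path <- file.path(store$spool, "blobs", req$key %||% "")
    if (!is_string(req$key %||% "") || !file.exists(path)) {
      return(fail("NOT_FOUND", sprintf("object \"%s\" not found", req$key %||% "")))
    }
    bytes <- readBin(path, "raw", file.info(path)$size)
    return(done(gw_ok(key = req$key, size = length(bytes), b64 = as.character(base64_enc(bytes))),
                sprintf("object get %s", req$key)))
  }
  if (op == "object_list") {
    if (cfg$type != "objectstore") return(fail("OTHER", "not an object store"))
    keys <- list.files(file.path(store$spool, "blobs"), recursive = TRUE)
    return(done(gw_ok(keys = as.list(keys)), "object list"))
  }
  fail("OTHER", sprintf("unknown operation '%s'", op))
}

# a FHIR entity record holds its resource in some list-valued attribute
extract_resource <- function(rec) {
  for (v in rec) if (is.list(v) && !is.null(v$resourceType)) return(v)
  rec
}

load_store <- function(spool_dir) {
  cfg <- fromJSON(file.path(spool_dir, "config.json"), simplifyVector = TRUE)
  data_dir <- file.path(spool_dir, "data")
  tables <- list()
  for (f in list.files(data_dir, pattern = "\\.json$")) {
    tables[[sub("\\.json$", "", f)]] <- fromJSON(file.path(data_dir, f), simplifyVector = FALSE)
  }
  list(config = cfg, tables = tables, spool = spool_dir)
}

#' Serve one provisioned data source (blocking)
#'
#' Runs the gateway accept loop for the source spooled at `spool_dir`.
#' Normally invoked in a background R process by [provision_provider()];
#' exposed so a fixture server can be started directly.
#'
#' @param spool_dir spool directory written at provisioning time.
#' @param max_requests stop after this many requests (default unlimited;
#'   the provisioner stops the server by signal at teardown).
#' @return not expected to return under default settings.
#' @export
serve_source <- function(spool_dir, max_requests = Inf) {
  store <- load_store(spool_dir)
  cfg <- store$config
  telemetry_file <- file.path(spool_dir, "telemetry.ndjson")
  ready_file <- file.path(spool_dir, "ready")
  writeLines(as.character(Sys.getpid()), file.path(spool_dir, "pid"))
  sock <- tryCatch(serverSocket(as.integer(cfg$port)), error = function(e) e)
  if (inherits(sock, "error")) {
    writeLines(paste0("err:", conditionMessage(sock)), ready_file)
    return(invisible(FALSE))
  }
  on.exit(close(sock), add = TRUE)
  writeLines(paste0("ok:", cfg$port), ready_file)

  served <- 0
  while (served < max_requests) {
    con <- tryCatch(socketAccept(sock, blocking = TRUE, open = "r+", timeout = 600),
                    error = function(e) NULL)
    if (is.null(con)) next
    served <- served + 1
    tryCatch({
      line <- readLines(con, n = 1, warn = FALSE)
      if (length(line) && nzchar(line)) {
        req <- tryCatch(fromJSON(line, simplifyVector = FALSE), error = function(e) NULL)
        if (is.null(req)) {
          out <- list(response = gw_err("SYNTAX", "request is not valid JSON"),
                      event = "QUERY_FAIL", error_class = "SYNTAX", detail = "bad request json")
        } else if (!identical(req$user %||% "", cfg$user) || !identical(req$password %||% "", cfg$password)) {
          out <- list(response = gw_err("OTHER", "authentication failed"),
                      event = "AUTH_FAIL", detail = sprintf("user '%s'", req$user %||% ""))
        } else {
          out <- gw_handle(req, store)
        }
        append_ndjson(telemetry_file,
                      telemetry_event(cfg$source_name, out$event, out$error_class %||% NA_character_,
                                      out$detail %||% ""))
        writeLines(canonical_json(out$response), con)
        flush(con)
      }
    }, error = function(e) {
      tryCatch(writeLines(canonical_json(gw_err("OTHER", conditionMessage(e))), con), error = function(e2) NULL)
    })
    tryCatch(close(con), error = function(e) NULL)
  }
  invisible(TRUE)
}

#' Entry point for a background source-server process
#'
#' Reads the spool directory from the command line; used by the provisioner
#' as `Rscript -e 'fedsmoke::run_source_server()' <spool_dir>`.
#' @return not expected to return.
#' @export
run_source_server <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  if (!length(args)) stop("usage: run_source_server <spool_dir>")
  serve_source(args[[1]])
}

# Parent-side line-protocol client. On TCP connection failure the client
# appends a CONNECT_FAIL event to the handle's telemetry log (the server
# cannot observe a connection that never reached it).
gateway_request <- function(host, port, payload, timeout = 10,
                            telemetry_file = NULL, source_name = "") {
  con <- tryCatch(
    suppressWarnings(socketConnection(host, as.integer(port), open = "r+", blocking = TRUE, timeout = timeout)),
    error = function(e) NULL)
  if (is.null(con)) {
    if (!is.null(telemetry_file)) {
      append_ndjson(telemetry_file, telemetry_event(source_name, "CONNECT_FAIL", "OTHER",
                                                    sprintf("connection to %s:%s refused", host, port)))
    }
    return(gw_err("OTHER", sprintf("connection to %s:%s refused", host, port)))
  }
  on.exit(close(con))
  writeLines(canonical_json(payload), con)
  flush(con)
  resp <- readLines(con, n = 1, warn = FALSE)
  if (!length(resp) || !nzchar(resp)) {
    if (!is.null(telemetry_file)) {
      append_ndjson(telemetry_file, telemetry_event(source_name, "CONNECT_FAIL", "OTHER", "no response"))
    }
    return(gw_err("OTHER", "no response from gateway"))
  }
  fromJSON(resp, simplifyVector = FALSE)
}
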