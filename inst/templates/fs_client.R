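# Gateway client for analysis code running inside a fedsmoke simulation.
# Self-contained (base R + jsonlite): analysis packages source this file and
# talk to their provider's data sources through the connection environment
# variables injected by the simulation engine.
#
# Protocol: one JSON object per line over TCP; responses carry ok = TRUE
# plus results, or ok = FALSE plus error_class/detail. Connection failures
# are appended to fs_client_events.ndjson in the working directory, where
# the engine picks them up as step evidence.

library(jsonlite)

.fs_events_file <- "fs_client_events.ndjson"

fs_event <- function(source, kind, error_class = NULL, detail = "") {
  rec <- list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), source = source,
              kind = kind, error_class = error_class, detail = detail)
  cat(as.character(toJSON(rec, auto_unbox = TRUE, null = "null")), "\n",
      sep = "", file = .fs_events_file, append = TRUE)
}

# read one source's connection variables (<NAME>_HOST, _PORT, _USER, ...)
fs_source <- function(name) {
  pre <- toupper(gsub("[^A-Za-z0-9]", "_", name))
  g <- function(s) Sys.getenv(paste0(pre, "_", s))
  list(name = name, host = g("HOST"), port = suppressWarnings(as.integer(g("PORT"))),
       user = g("USER"), password = g("PASSWORD"), type = g("TYPE"))
}

fs_request <- function(src, payload, timeout = 10) {
  payload$user <- src$user
  payload$password <- src$password
  con <- tryCatch(
    suppressWarnings(socketConnection(src$host, src$port, open = "r+", blocking = TRUE, timeout = timeout)),
    error = function(e) NULL)
  if (is.null(con)) {
    fs_event(src$name, "CONNECT_FAIL", "OTHER",
             sprintf("connection to %s:%s refused", src$host, src$port))
    return(list(ok = FALSE, error_class = "OTHER", detail = "connection refused"))
  }
  on.exit(close(con))
  writeLines(as.character(toJSON(payload, auto_unbox = TRUE, null = "null", digits = NA)), con)
  flush(con)
  resp <- readLines(con, n = 1, warn = FALSE)
  if (!length(resp) || !nzchar(resp)) {
    fs_event(src$name, "CONNECT_FAIL", "OTHER", "no response from gateway")
    return(list(ok = FALSE, error_class = "OTHER", detail = "no response"))
  }
  fromJSON(resp, simplifyVector = FALSE)
}

fs_connect <- function(src) isTRUE(fs_request(src, list(op = "ping"))$ok)
fs_query_sql <- function(src, sql) fs_request(src, list(op = "query", sql = sql))
fs_doc_query <- function(src, entity, filter = NULL) fs_request(src, list(op = "docquery", entity = entity, filter = filter))
fs_fhir_types <- function(src) fs_request(src, list(op = "fhir_meta"))
fs_fhir_list <- function(src, type) fs_request(src, list(op = "fhir_list", type = type))
fs_fhir_get <- function(src, type, id) fs_request(src, list(op = "fhir_get", type = type, id = id))
fs_get_object <- function(src, key) {
  r <- fs_request(src, list(op = "object_get", key = key))
  if (isTRUE(r$ok)) r$bytes <- base64_dec(r$b64)
  r
}

# scalar value of a single-aggregate SQL result
fs_agg_value <- function(resp) {
  if (!isTRUE(resp$ok)) return(NULL)
  resp$rows[[1]][[1]]
}

fs_read_json <- function(path) {
  if (!file.exists(path) || file.info(path)$size == 0) return(NULL)
  tryCatch(fromJSON(path, simplifyVector = FALSE), error = function(e) NULL)
}

fs_write_json <- function(x, path) {
  if (!dir.exists(dirname(path))) dir.create(dirname(path), recursive = TRUE)
  write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
}
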