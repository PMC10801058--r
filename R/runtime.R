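# Analysis runtime: loads analysis packages (user code + manifest), prepares
# throwaway workspaces, executes the entrypoint as an isolated child process
# with a scrubbed environment, and snapshots the workspace `state/` subtree
# afterwards -- the desk-scale analogue of stopping an analysis container
# and re-instantiating the next one from it.

MANIFEST_FILE <- "fedsmoke.yaml"
DEFAULT_RESULT_PATH <- "state/results.json"
CLIENT_EVENTS_FILE <- "fs_client_events.ndjson"

# environment a child process always receives, beyond injected credentials;
# R additionally sets its own R_* runtime variables
baseline_env_names <- function() c("PATH", "HOME", "R_LIBS", "TMPDIR", "RESULT_PATH")

#' Load an analysis package
#'
#' An analysis package is a directory of user code plus a `fedsmoke.yaml`
#' manifest declaring how to run it:
#' \describe{
#'   \item{entrypoint}{command vector executed per provider, e.g.
#'     `["Rscript", "analysis.R"]` (required).}
#'   \item{setup}{optional one-time build command run once per simulation.}
#'   \item{aggregator_entrypoint}{command vector for the aggregation step;
#'     required for FL / FL-INC.}
#'   \item{result_path}{workspace-relative path of the result artifact
#'     (default `state/results.json`), exported as `RESULT_PATH`.}
#'   \item{result_format}{`json` (default) or `bytes`.}
#'   \item{env}{named map of static variables passed to every execution.}
#' }
#'
#' @param path package directory.
#' @return an object of class `fs_analysis_package`.
#' @export
load_package <- function(path) {
  if (!dir.exists(path)) fs_abort("manifest_missing", sprintf("package directory '%s' does not exist", path))
  mpath <- file.path(path, MANIFEST_FILE)
  if (!file.exists(mpath)) fs_abort("manifest_missing", sprintf("no %s in '%s'", MANIFEST_FILE, path))
  m <- tryCatch(yaml::read_yaml(mpath), error = function(e) {
    fs_abort("manifest_invalid", sprintf("cannot parse %s: %s", MANIFEST_FILE, conditionMessage(e)))
  })
  entry <- as.character(m$entrypoint %||% character(0))
  if (!length(entry)) fs_abort("manifest_invalid", "manifest declares no entrypoint")
  result_path <- m$result_path %||% DEFAULT_RESULT_PATH
  if (grepl("^/", result_path) || grepl("\\.\\.", result_path)) {
    fs_abort("manifest_invalid", "result_path must be a relative path inside the workspace")
  }
  result_format <- m$result_format %||% "json"
  if (!result_format %in% c("json", "bytes")) fs_abort("manifest_invalid", "result_format must be json or bytes")
  entry_file <- entry[length(entry)]
  if (!file.exists(file.path(path, entry_file))) {
    fs_abort("entrypoint_missing", sprintf("entrypoint file '%s' not found in package", entry_file))
  }
  manifest <- list(entrypoint = entry,
                   setup = if (!is.null(m$setup)) as.character(m$setup),
                   aggregator_entrypoint = if (!is.null(m$aggregator_entrypoint)) as.character(m$aggregator_entrypoint),
                   result_path = result_path, result_format = result_format,
                   env = m$env %||% list())
  structure(list(root = normalizePath(path), manifest = manifest), class = "fs_analysis_package")
}

copy_tree <- function(from, to) {
  dir.create(to, recursive = TRUE, showWarnings = FALSE)
  entries <- list.files(from, all.files = TRUE, no.. = TRUE, full.names = TRUE)
  for (e in entries) file.copy(e, to, recursive = TRUE)
}

#' Prepare a fresh workspace for one execution
#'
#' Copies the package root into a throwaway directory and overlays the
#' `state/` subtree of `base_state` (the snapshot carried over from the
#' previous execution), reproducing container-state carry-over semantics.
#'
#' @param package an [load_package()] result.
#' @param base_state optional `fs_workspace_state` whose `state/` is overlaid.
#' @param dir workspace directory to create (default: a temp dir).
#' @param run_setup if `TRUE` and the manifest declares `setup`, run it now
#'   (once per simulation); a nonzero setup exit raises `SetupFailed`.
#' @return workspace path.
#' @export
prepare_workspace <- function(package, base_state = NULL, dir = NULL, run_setup = FALSE) {
  stopifnot(inherits(package, "fs_analysis_package"))
  ws <- dir %||% tempfile("fs-ws-")
  copy_tree(package$root, ws)
  if (!is.null(base_state)) {
    stopifnot(inherits(base_state, "fs_workspace_state"))
    if (!identical(md5_tree(base_state$dir), base_state$digest)) {
      fs_abort("state_corrupt", "workspace state digest does not verify")
    }
    if (dir.exists(base_state$dir)) copy_tree(base_state$dir, file.path(ws, "state"))
  }
  if (run_setup && !is.null(package$manifest$setup)) {
    code <- run_child(ws, env_vars = character(0), command = package$manifest$setup,
                      timeout = 300, tag = "setup", wait = TRUE)$exit_code
    if (code != 0) fs_abort("setup_failed", sprintf("setup command exited with code %d", code))
  }
  ws
}

#' Snapshot a workspace's carried state
#'
#' Captures the `state/` subtree as an immutable, content-addressed
#' snapshot; this is what the next execution is seeded from.
#'
#' @param workspace workspace path.
#' @param lineage free-form tag (round/hop) recorded on the snapshot.
#' @return an object of class `fs_workspace_state` (`dir`, `digest`, `lineage`).
#' @export
snapshot_workspace <- function(workspace, lineage = "") {
  snap <- tempfile("fs-state-")
  src <- file.path(workspace, "state")
  if (dir.exists(src)) {
    dir.create(snap, recursive = TRUE)
    entries <- list.files(src, all.files = TRUE, no.. = TRUE, full.names = TRUE)
    for (e in entries) file.copy(e, snap, recursive = TRUE)
  } else {
    dir.create(snap, recursive = TRUE)
  }
  structure(list(dir = snap, digest = md5_tree(snap), lineage = lineage),
            class = "fs_workspace_state")
}

# assemble and launch a child command; returns an execution handle
run_child <- function(workspace, env_vars, command, timeout, tag = "run", wait = FALSE) {
  stopifnot(dir.exists(workspace), length(command) >= 1)
  base <- c(PATH = Sys.getenv("PATH"), HOME = Sys.getenv("HOME"),
            R_LIBS = paste(.libPaths(), collapse = ":"), TMPDIR = tempdir())
  env_all <- c(base, env_vars)
  env_str <- paste(sprintf("%s=%s", names(env_all), vapply(unname(env_all), shQuote, "")), collapse = " ")
  cmd_str <- paste(vapply(command, shQuote, ""), collapse = " ")
  marker <- paste0(".fs_", tag)
  script <- sprintf("cd %s && env -i %s timeout %d %s > %s_stdout 2> %s_stderr; echo $? > %s_exit",
                    shQuote(workspace), env_str, as.integer(ceiling(timeout)), cmd_str,
                    marker, marker, marker)
  handle <- list(workspace = workspace, marker = marker, started = Sys.time(),
                 timeout = timeout, env_vars = env_vars, tag = tag)
  unlink(file.path(workspace, paste0(marker, c("_exit", "_stdout", "_stderr"))))
  system(script, wait = wait)
  if (wait) handle$exit_code <- read_exit(handle)
  handle
}

read_exit <- function(handle) {
  f <- file.path(handle$workspace, paste0(handle$marker, "_exit"))
  if (!file.exists(f)) return(NA_integer_)
  v <- suppressWarnings(as.integer(readLines(f, warn = FALSE)[1]))
  v
}

exec_finished <- function(handle) !is.na(read_exit(handle))

# wait for a set of execution handles; records per-handle completion times
# (used to measure observed concurrency) and returns them
wait_executions <- function(handles, poll = 0.02) {
  deadline <- max(vapply(handles, function(h) h$timeout, 0)) + 30
  t0 <- Sys.time()
  ended <- rep(as.POSIXct(NA), length(handles))
  repeat {
    done <- vapply(handles, exec_finished, TRUE)
    ended[done & is.na(ended)] <- Sys.time()
    if (all(done) || as.numeric(difftime(Sys.time(), t0, units = "secs")) > deadline) break
    Sys.sleep(poll)
  }
  ended[is.na(ended)] <- Sys.time()
  list(exit = vapply(handles, read_exit, 0L), ended = ended)
}

read_text <- function(path) {
  if (!file.exists(path)) return("")
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' Collect the result artifact of an execution
#'
#' Looks up the manifest's `result_path` in the run's workspace snapshot (or
#' workspace). Absence and corruption are reported, never thrown: the smoke
#' criteria treat them as evidence.
#'
#' @param outcome an `fs_run_outcome` (or a workspace path).
#' @param manifest the package manifest.
#' @return list with `status` (`"ok"`, `"absent"` or `"corrupt"`), `path`,
#'   `raw` bytes and `parsed` (for `result_format = "json"`).
#' @export
collect_result <- function(outcome, manifest) {
  ws <- if (inherits(outcome, "fs_run_outcome")) outcome$workspace else outcome
  rel <- manifest$result_path %||% DEFAULT_RESULT_PATH
  path <- file.path(ws, rel)
  if (!file.exists(path) || file.info(path)$size == 0) {
    return(list(status = "absent", path = rel, raw = NULL, parsed = NULL))
  }
  raw <- readBin(path, "raw", file.info(path)$size)
  if (identical(manifest$result_format %||% "json", "json")) {
    parsed <- tryCatch(fromJSON(rawToChar(raw), simplifyVector = FALSE), error = function(e) NULL)
    if (is.null(parsed)) return(list(status = "corrupt", path = rel, raw = raw, parsed = NULL))
    return(list(status = "ok", path = rel, raw = raw, parsed = parsed))
  }
  list(status = "ok", path = rel, raw = raw, parsed = NULL)
}

finish_execution <- function(handle, manifest, lineage = "", ended = NULL) {
  ws <- handle$workspace
  exit_code <- read_exit(handle)
  timed_out <- !is.na(exit_code) && exit_code == 124L
  state <- snapshot_workspace(ws, lineage)
  result <- collect_result(ws, manifest)
  client_events <- read_ndjson(file.path(ws, CLIENT_EVENTS_FILE))
  ended <- ended %||% Sys.time()
  outcome <- list(
    exit_code = if (is.na(exit_code)) 137L else exit_code,
    timed_out = timed_out || is.na(exit_code),
    stdout = read_text(file.path(ws, paste0(handle$marker, "_stdout"))),
    stderr = read_text(file.path(ws, paste0(handle$marker, "_stderr"))),
    started = handle$started, ended = ended,
    duration = as.numeric(difftime(ended, handle$started, units = "secs")),
    workspace = ws, workspace_state = state, result = result,
    client_events = client_events, env_vars = handle$env_vars)
  class(outcome) <- "fs_run_outcome"
  outcome
}

#' Execute an analysis entrypoint in a prepared workspace
#'
#' Runs the command as an isolated child process: scrubbed environment
#' (baseline interpreter variables, the supplied variables, nothing else),
#' working directory = the workspace, wall-clock limit enforced. Analysis
#' failure is data, not an exception: the exit code, output streams,
#' resulting workspace snapshot and result-artifact status are captured in
#' the outcome. A timeout surfaces as the distinguished exit code 124.
#'
#' @param workspace a [prepare_workspace()] result.
#' @param env named character vector injected into the child (one provider's
#'   connection variables plus `RESULT_PATH`).
#' @param manifest the package manifest (for entrypoint and result path).
#' @param timeout seconds before the child is killed.
#' @param command command vector; defaults to the manifest entrypoint.
#' @param lineage tag recorded on the workspace snapshot.
#' @return an object of class `fs_run_outcome`.
#' @export
execute_step <- function(workspace, env, manifest, timeout = 300,
                         command = NULL, lineage = "") {
  command <- command %||% manifest$entrypoint
  if (!"RESULT_PATH" %in% names(env)) {
    env <- c(env, RESULT_PATH = manifest$result_path %||% DEFAULT_RESULT_PATH)
  }
  handle <- run_child(workspace, env, command, timeout)
  w <- wait_executions(list(handle))
  finish_execution(handle, manifest, lineage, ended = w$ended[1])
}
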