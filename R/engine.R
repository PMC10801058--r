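# Simulation engine: orchestrates a full distributed-analytics simulation
# over provisioned providers and maps every execution onto the six abstract
# workflow steps:
#   S1 connect to the data source     S4 run the analysis
#   S2 query the data                 S5 store the result artifact
#   S3 load previous results /        S6 aggregate intermediate results
#      initialize                        (aggregation paradigms only)
#
# Paradigms: IIL (sequential; the analysis travels provider to provider,
# each hop re-instantiated from the previous hop's workspace state), FL
# (one replica per provider per round, executed in parallel, plus a central
# aggregation), FL-INC (FL with at most one replica running at a time).

PARADIGMS <- c("IIL", "FL", "FL_INC")
STEPS <- paste0("S", 1:6)
AGGREGATOR_ID <- "AGGREGATOR"

#' Simulation configuration
#'
#' @param paradigm `"IIL"`, `"FL"` or `"FL_INC"`.
#' @param rounds number of rounds (each round repeats S1..S5 at every
#'   provider, plus S6 under aggregation paradigms).
#' @param order provider visit order (default: schema declaration order).
#' @param seed root seed for datasets, credentials and ports.
#' @param n_per_entity synthetic records generated per entity.
#' @param timeout per-execution wall-clock limit in seconds.
#' @param aggregate_partial if `TRUE`, aggregation is still attempted when a
#'   replica failed (default `FALSE`: a failed replica fails S6).
#' @param connection_faults named list provider_id -> `"WRONG_PORT"` or
#'   `"BAD_CREDENTIALS"`, injected into that provider's connection variables
#'   (fault-injection hook used by the scenario bundles).
#' @param strict if `TRUE`, unobserved criteria withhold an overall PASS.
#' @return an object of class `fs_sim_config`.
#' @export
simulation_config <- function(paradigm = "IIL", rounds = 1L, order = NULL, seed = 1L,
                              n_per_entity = 10L, timeout = 120, aggregate_partial = FALSE,
                              connection_faults = list(), strict = TRUE) {
  if (!paradigm %in% PARADIGMS) fs_abort("config_invalid", sprintf("unknown paradigm '%s'", paradigm))
  if (!is_count(rounds)) fs_abort("config_invalid", "rounds must be a positive integer")
  if (!is_count(n_per_entity)) fs_abort("config_invalid", "n_per_entity must be a positive integer")
  structure(list(paradigm = paradigm, rounds = as.integer(rounds), order = order,
                 seed = as.integer(seed), n_per_entity = as.integer(n_per_entity),
                 timeout = timeout, aggregate_partial = isTRUE(aggregate_partial),
                 connection_faults = connection_faults, strict = isTRUE(strict)),
            class = "fs_sim_config")
}

step_event <- function(round, provider, step, status, detail = "", evidence = list()) {
  list(round = round, provider = provider, step = step, status = status,
       detail = detail, evidence = evidence)
}

events_frame <- function(events) {
  if (!length(events)) {
    return(data.frame(round = integer(0), provider = character(0), step = character(0),
                      status = character(0), detail = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(events, function(e) {
    data.frame(round = e$round, provider = e$provider, step = e$step, status = e$status,
               detail = e$detail, stringsAsFactors = FALSE)
  }))
  df$evidence <- lapply(events, `[[`, "evidence")
  df
}

# telemetry rows appended to a provider's sources since the given offsets
telemetry_delta <- function(handles, offsets) {
  rows <- list()
  for (nm in names(handles)) {
    ev <- source_telemetry(handles[[nm]])
    from <- offsets[[nm]] %||% 0L
    if (nrow(ev) > from) rows[[nm]] <- ev[(from + 1L):nrow(ev), , drop = FALSE]
  }
  if (!length(rows)) {
    return(data.frame(ts = character(0), source = character(0), kind = character(0),
                      error_class = character(0), detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

telemetry_offsets <- function(handles) {
  lapply(handles, function(h) nrow(source_telemetry(h)))
}

#' Map an execution outcome onto step events S1-S5
#'
#' Statuses are derived from the evidence each step leaves behind: S1 from
#' CONNECT/AUTH telemetry, S2 from QUERY telemetry (schema-classified
#' failures fail the step), S3 from state presence (initialization on the
#' first execution, a non-empty prior result artifact afterwards), S4 from
#' the exit code, S5 from result-artifact collection. Steps downstream of
#' the first failure are marked `SKIP`; steps an external proxy source
#' cannot evidence are `UNOBSERVED`.
#'
#' @param outcome an `fs_run_outcome`.
#' @param telemetry data.frame of gateway telemetry for this execution
#'   (server-side delta plus the workspace's client-side events).
#' @param position list with `round`, `provider`, `initial` (first
#'   execution of the simulation), `prior_present` (result artifact present
#'   at workspace start) and `external` (source without gateway telemetry).
#' @return list of step events.
#' @export
map_outcome_to_steps <- function(outcome, telemetry, position) {
  k <- telemetry$kind %||% character(0)
  classes <- unique(telemetry$error_class[!is.na(telemetry$error_class)])
  connect_fail <- any(k %in% c("CONNECT_FAIL", "AUTH_FAIL"))
  query_fail <- any(k == "QUERY_FAIL")

  s1 <- if (connect_fail) "FAIL" else if (any(k == "CONNECT_OK")) "OK"
        else if (isTRUE(position$external)) "UNOBSERVED" else "UNOBSERVED"
  s2 <- if (query_fail) "FAIL" else if (any(k == "QUERY_OK")) "OK" else "UNOBSERVED"
  s3 <- if (isTRUE(position$initial)) "OK" else if (isTRUE(position$prior_present)) "OK" else "FAIL"
  s4 <- if (outcome$exit_code == 0L) "OK" else "FAIL"
  s5 <- if (identical(outcome$result$status, "ok")) "OK" else "FAIL"
  statuses <- c(S1 = s1, S2 = s2, S3 = s3, S4 = s4, S5 = s5)

  first_fail <- match("FAIL", statuses)
  if (!is.na(first_fail) && first_fail < 5L) {
    later <- seq.int(first_fail + 1L, 5L)
    statuses[later] <- "SKIP"
  }

  details <- c(
    S1 = if (connect_fail) paste(unique(telemetry$detail[k %in% c("CONNECT_FAIL", "AUTH_FAIL")]), collapse = "; ") else "",
    S2 = if (query_fail) paste(unique(telemetry$detail[k == "QUERY_FAIL"]), collapse = "; ") else "",
    S3 = if (statuses[["S3"]] == "FAIL") "no prior result artifact present at workspace start" else
         if (isTRUE(position$initial)) "initial execution (initialization)" else "prior result artifact present",
    S4 = if (outcome$timed_out) "execution timed out" else sprintf("exit code %d", outcome$exit_code),
    S5 = sprintf("result artifact %s at %s", outcome$result$status, outcome$result$path))

  evidence <- list(
    S1 = list(kinds = unique(k[k %in% c("CONNECT_OK", "CONNECT_FAIL", "AUTH_FAIL")])),
    S2 = list(kinds = unique(k[k %in% c("QUERY_OK", "QUERY_FAIL")]), error_classes = as.list(classes)),
    S3 = list(initial = isTRUE(position$initial), prior_present = isTRUE(position$prior_present)),
    S4 = list(exit_code = outcome$exit_code, timed_out = outcome$timed_out,
              stderr_tail = tail(strsplit(outcome$stderr, "\n")[[1]], 3)),
    S5 = list(status = outcome$result$status, path = outcome$result$path))

  lapply(STEPS[1:5], function(st) {
    step_event(position$round, position$provider, st, unname(statuses[[st]]),
               detail = unname(details[[st]]), evidence = evidence[[st]])
  })
}

client_events_frame <- function(outcome) {
  ev <- outcome$client_events
  if (!length(ev)) {
    return(data.frame(ts = character(0), source = character(0), kind = character(0),
                      error_class = character(0), detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(ev, function(e) {
    data.frame(ts = e$ts %||% "", source = e$source %||% "", kind = e$kind %||% "",
               error_class = e$error_class %||% NA_character_, detail = e$detail %||% "",
               stringsAsFactors = FALSE)
  }))
}

apply_connection_fault <- function(env, fault, handles) {
  if (is.null(fault)) return(env)
  for (nm in names(handles)) {
    pre <- env_prefix(handles[[nm]]$source_name)
    if (fault == "WRONG_PORT") env[[paste0(pre, "_PORT")]] <- "1"
    if (fault == "BAD_CREDENTIALS") env[[paste0(pre, "_PASSWORD")]] <- "not-the-password"
  }
  env
}

skip_events <- function(round, provider, reason) {
  lapply(STEPS[1:5], function(st) step_event(round, provider, st, "SKIP", detail = reason))
}

#' Simulate a distributed-analytics execution
#'
#' Provisions every provider with a seeded synthetic dataset, executes the
#' analysis package under the configured paradigm, and returns the complete
#' execution trace. Failures inside the analysis surface as FAIL step
#' events, not exceptions; sources are always torn down.
#'
#' @param config a [simulation_config()].
#' @param schemas list of [provider_schema()] objects.
#' @param package an [load_package()] result.
#' @param registry plugin registry (default: built-ins).
#' @param external_handles optional named list provider_id -> list of
#'   already-attached external source handles used instead of provisioning.
#' @return an object of class `fs_trace`.
#' @export
simulate <- function(config, schemas, package, registry = default_registry(),
                     external_handles = NULL) {
  stopifnot(inherits(config, "fs_sim_config"), inherits(package, "fs_analysis_package"))
  provider_ids <- vapply(schemas, `[[`, "", "provider_id")
  order <- config$order %||% c(provider_ids, names(external_handles %||% list()))
  all_ids <- c(provider_ids, names(external_handles %||% list()))
  if (!setequal(order, all_ids) || anyDuplicated(order)) {
    fs_abort("config_invalid", "provider order must be a permutation of the provisioned providers")
  }
  if (config$paradigm %in% c("FL", "FL_INC") && is.null(package$manifest$aggregator_entrypoint)) {
    fs_abort("config_invalid", sprintf("paradigm %s requires aggregator_entrypoint in the manifest", config$paradigm))
  }
  for (schema in schemas) {
    diags <- validate_provider_schema(schema, registry)
    if (nrow(diags)) fs_abort("invalid_schema", paste(diags$message, collapse = "; "))
  }

  datasets <- list()
  providers <- list()
  on.exit(for (p in providers) teardown_provider(p), add = TRUE)
  for (schema in schemas) {
    pid <- schema$provider_id
    datasets[[pid]] <- generate_dataset(schema, config$n_per_entity,
                                        derive_seed(config$seed, pid), registry)
    providers[[pid]] <- provision_provider(schema, datasets[[pid]], registry)
  }
  for (pid in names(external_handles %||% list())) providers[[pid]] <- external_handles[[pid]]
  is_external <- vapply(providers, function(hs) isTRUE(hs[[1]]$external), TRUE)

  # one-time setup (build analogue): run in a scratch workspace, cached
  if (!is.null(package$manifest$setup)) prepare_workspace(package, run_setup = TRUE)

  events <- list()
  outcomes <- list()
  final_result <- NULL
  add_events <- function(evs) events[seq_along(evs) + length(events)] <<- evs
  record_outcome <- function(provider, round, role, outcome) {
    outcomes[[length(outcomes) + 1L]] <<- list(
      provider = provider, round = round, role = role,
      exit_code = outcome$exit_code, duration = outcome$duration,
      started = outcome$started, ended = outcome$ended,
      state_digest = outcome$workspace_state$digest,
      result_status = outcome$result$status,
      env_names = names(outcome$env_vars))
  }

  manifest <- package$manifest
  result_rel <- manifest$result_path
  static_env <- vapply(manifest$env, as.character, "")
  if (length(static_env)) names(static_env) <- names(manifest$env)

  exec_env <- function(pid) {
    env <- c(provider_conn_env(providers[[pid]]), static_env,
             RESULT_PATH = result_rel, FS_PARADIGM = config$paradigm)
    apply_connection_fault(env, config$connection_faults[[pid]], providers[[pid]])
  }

  run_one <- function(pid, round, base_state, initial) {
    offs <- if (!is_external[[pid]]) telemetry_offsets(providers[[pid]]) else NULL
    ws <- prepare_workspace(package, base_state)
    prior_present <- file.exists(file.path(ws, result_rel)) &&
      file.info(file.path(ws, result_rel))$size > 0
    outcome <- execute_step(ws, exec_env(pid), manifest, timeout = config$timeout,
                            lineage = sprintf("round%d/%s", round, pid))
    telem <- rbind(if (!is_external[[pid]]) telemetry_delta(providers[[pid]], offs) else NULL,
                   client_events_frame(outcome))
    evs <- map_outcome_to_steps(outcome, telem,
                                list(round = round, provider = pid, initial = initial,
                                     prior_present = prior_present,
                                     external = is_external[[pid]]))
    list(outcome = outcome, events = evs)
  }

  if (config$paradigm == "IIL") {
    state <- NULL
    terminated <- FALSE
    for (r in seq_len(config$rounds)) {
      for (h in seq_along(order)) {
        pid <- order[h]
        if (terminated) {
          add_events(skip_events(r, pid, "skipped: earlier execution failed"))
          next
        }
        res <- run_one(pid, r, state, initial = (r == 1L && h == 1L))
        add_events(res$events)
        record_outcome(pid, r, "hop", res$outcome)
        statuses <- vapply(res$events, `[[`, "", "status")
        if (any(statuses == "FAIL")) {
          terminated <- TRUE
        } else {
          state <- res$outcome$workspace_state
          final_result <- res$outcome$result
        }
      }
    }
  } else {
    concurrency <- if (config$paradigm == "FL_INC") 1L else length(order)
    global_state <- NULL
    terminated <- FALSE
    for (r in seq_len(config$rounds)) {
      if (terminated) {
        for (pid in order) add_events(skip_events(r, pid, "skipped: earlier round failed"))
        add_events(list(step_event(r, AGGREGATOR_ID, "S6", "SKIP", "skipped: earlier round failed")))
        next
      }
      round_fail <- FALSE
      agg_input <- tempfile(sprintf("fs-agg-r%d-", r))
      dir.create(agg_input, recursive = TRUE)

      run_replica_batch <- function(pids) {
        offs <- lapply(pids, function(pid) if (!is_external[[pid]]) telemetry_offsets(providers[[pid]]))
        names(offs) <- pids
        wss <- lapply(pids, function(pid) prepare_workspace(package, global_state))
        names(wss) <- pids
        handles <- lapply(pids, function(pid) {
          run_child(wss[[pid]], c(exec_env(pid)), manifest$entrypoint, config$timeout)
        })
        w <- wait_executions(handles)
        lapply(seq_along(pids), function(i) {
          pid <- pids[i]
          outcome <- finish_execution(handles[[i]], manifest,
                                      lineage = sprintf("round%d/%s", r, pid), ended = w$ended[i])
          prior_present <- !is.null(global_state)
          telem <- rbind(if (!is_external[[pid]]) telemetry_delta(providers[[pid]], offs[[pid]]) else NULL,
                         client_events_frame(outcome))
          evs <- map_outcome_to_steps(outcome, telem,
                                      list(round = r, provider = pid, initial = (r == 1L),
                                           prior_present = prior_present,
                                           external = is_external[[pid]]))
          list(pid = pid, outcome = outcome, events = evs)
        })
      }

      batches <- if (concurrency == 1L) as.list(order) else list(order)
      results <- list()
      for (b in batches) results <- c(results, run_replica_batch(b))

      for (res in results) {
        add_events(res$events)
        record_outcome(res$pid, r, "replica", res$outcome)
        if (any(vapply(res$events, `[[`, "", "status") == "FAIL")) round_fail <- TRUE
        if (identical(res$outcome$result$status, "ok")) {
          pdir <- file.path(agg_input, res$pid)
          dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
          file.copy(file.path(res$outcome$workspace, result_rel),
                    file.path(pdir, basename(result_rel)))
        }
      }

      if (round_fail && !config$aggregate_partial) {
        add_events(list(step_event(r, AGGREGATOR_ID, "S6", "FAIL",
                                   "aggregation not attempted: replica failure in this round")))
        terminated <- TRUE
        next
      }
      agg_ws <- prepare_workspace(package)
      agg_outcome <- execute_step(agg_ws,
                                  c(AGGREGATION_INPUT_DIR = agg_input, static_env,
                                    RESULT_PATH = result_rel),
                                  manifest, timeout = config$timeout,
                                  command = manifest$aggregator_entrypoint,
                                  lineage = sprintf("round%d/aggregator", r))
      record_outcome(AGGREGATOR_ID, r, "aggregator", agg_outcome)
      agg_ok <- agg_outcome$exit_code == 0L && identical(agg_outcome$result$status, "ok")
      add_events(list(step_event(r, AGGREGATOR_ID, "S6", if (agg_ok) "OK" else "FAIL",
                                 detail = if (agg_ok) "global result stored"
                                          else sprintf("aggregator exit %d, artifact %s",
                                                       agg_outcome$exit_code, agg_outcome$result$status),
                                 evidence = list(exit_code = agg_outcome$exit_code,
                                                 artifact = agg_outcome$result$status,
                                                 stderr_tail = tail(strsplit(agg_outcome$stderr, "\n")[[1]], 3)))))
      if (agg_ok) {
        global_state <- agg_outcome$workspace_state
        final_result <- agg_outcome$result
      } else {
        terminated <- TRUE
      }
    }
  }

  structure(list(config = config, provider_order = order, events = events_frame(events),
                 outcomes = outcomes, final_result = final_result,
                 dataset_digests = lapply(datasets, dataset_digest),
                 external = is_external, created = Sys.time()),
            class = "fs_trace")
}

#' Executions recorded in a trace
#' @param trace an `fs_trace`.
#' @return integer count of analysis/aggregator executions.
#' @export
trace_executions <- function(trace) length(trace$outcomes)

#' Maximum observed execution concurrency in a trace
#'
#' Computed from the recorded start/end intervals of all executions.
#' @param trace an `fs_trace`.
#' @return integer: the maximum number of simultaneously running executions.
#' @export
trace_max_concurrency <- function(trace) {
  if (!length(trace$outcomes)) return(0L)
  times <- lapply(trace$outcomes, function(o) c(as.numeric(o$started), as.numeric(o$ended)))
  events <- do.call(rbind, lapply(times, function(t) {
    rbind(c(t[1], 1L), c(t[2], -1L))
  }))
  events <- events[order(events[, 1], events[, 2]), , drop = FALSE]
  max(cumsum(events[, 2]))
}

# timestamp-free canonical form used for determinism comparisons
trace_comparable <- function(trace) {
  outs <- lapply(trace$outcomes, function(o) {
    o[c("provider", "round", "role", "exit_code", "state_digest", "result_status")]
  })
  ev <- trace$events
  list(paradigm = trace$config$paradigm, rounds = trace$config$rounds,
       seed = trace$config$seed, n_per_entity = trace$config$n_per_entity,
       provider_order = trace$provider_order,
       events = ev[, c("round", "provider", "step", "status", "detail")],
       outcomes = outs,
       final_result = trace$final_result$parsed,
       dataset_digests = trace$dataset_digests)
}

#' Serialize a trace as JSON
#' @param trace an `fs_trace`.
#' @param path optional output file.
#' @param include_timestamps include the wall-clock metadata block.
#' @return JSON string, invisibly if written to `path`.
#' @export
trace_to_json <- function(trace, path = NULL, include_timestamps = TRUE) {
  body <- trace_comparable(trace)
  if (include_timestamps) {
    body$meta <- list(created = format(trace$created, "%Y-%m-%dT%H:%M:%S"),
                      durations = vapply(trace$outcomes, function(o) round(o$duration, 3), 0))
  }
  out <- as.character(toJSON(body, auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows"))
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Compare two traces ignoring timing
#' @param a,b `fs_trace` objects.
#' @return `TRUE` if the traces are identical up to timestamps/durations.
#' @export
traces_equal <- function(a, b) {
  identical(canonical_json(trace_comparable(a)), canonical_json(trace_comparable(b)))
}

#' @export
print.fs_trace <- function(x, ...) {
  cat(sprintf("<fs_trace> %s, %d round(s), %d provider(s), %d execution(s)\n",
              x$config$paradigm, x$config$rounds, length(x$provider_order), length(x$outcomes)))
  tab <- table(x$events$status)
  cat("  step events:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
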