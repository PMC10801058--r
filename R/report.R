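# Requirement evaluation: maps the execution trace onto the six smoke-test
# requirements, one per workflow step:
#   A proper connection interface        (S1)
#   B matching data schema               (S2)
#   C previous results loaded / init     (S3)
#   D analysis execution without errors  (S4)
#   E successful result storage          (S5)
#   F successful result aggregation      (S6, aggregation paradigms only)

#' The requirement catalogue
#' @return data.frame with columns `code`, `step`, `title`.
#' @export
requirement_table <- function() {
  data.frame(
    code = LETTERS[1:6],
    step = paste0("S", 1:6),
    title = c("Proper connection interface",
              "Matching schema",
              "Load previous (intermediate) results",
              "Analysis execution without errors",
              "Successful result storage",
              "Successful result aggregation"),
    stringsAsFactors = FALSE)
}

status_to_verdict <- c(OK = "PASS", FAIL = "FAIL", SKIP = "SKIP", UNOBSERVED = "UNOBSERVED")

#' Evaluate the smoke-test requirements against a trace
#'
#' Every step event becomes one per-requirement, per-provider, per-round
#' outcome (`PASS`/`FAIL`/`SKIP`/`UNOBSERVED`). Requirement F outcomes exist
#' only under aggregation paradigms. The overall verdict is `FAIL` if any
#' outcome failed, otherwise `UNOBSERVED` if strict mode is on and a
#' requirement could not be observed, otherwise `PASS`.
#'
#' @param trace an `fs_trace` from [simulate()].
#' @return an object of class `fs_smoke_report`.
#' @export
evaluate_trace <- function(trace) {
  if (!inherits(trace, "fs_trace") || is.null(trace$events)) {
    fs_abort("trace_incomplete", "need a complete fs_trace")
  }
  reqs <- requirement_table()
  ev <- trace$events
  ev$requirement <- reqs$code[match(ev$step, reqs$step)]
  outcomes <- data.frame(requirement = ev$requirement, provider = ev$provider,
                         round = ev$round, status = unname(status_to_verdict[ev$status]),
                         detail = ev$detail, stringsAsFactors = FALSE)
  outcomes$evidence <- ev$evidence
  outcomes <- outcomes[order(match(outcomes$requirement, LETTERS), outcomes$round,
                             match(outcomes$provider, c(trace$provider_order, AGGREGATOR_ID))), ]
  rownames(outcomes) <- NULL

  verdict <- if (any(outcomes$status == "FAIL")) "FAIL"
             else if (isTRUE(trace$config$strict) && any(outcomes$status == "UNOBSERVED")) "UNOBSERVED"
             else "PASS"

  report <- structure(list(
    config = list(paradigm = trace$config$paradigm, rounds = trace$config$rounds,
                  seed = trace$config$seed, n_per_entity = trace$config$n_per_entity,
                  strict = trace$config$strict, provider_order = trace$provider_order),
    outcomes = outcomes, verdict = verdict,
    meta = list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "fs_smoke_report")
  fails <- which(outcomes$status == "FAIL")
  report$diagnostics <- vapply(fails, function(i) classify_failure(outcomes[i, ], trace), "")
  report
}

#' Human-readable diagnosis of a failed requirement outcome
#'
#' @param outcome one row of a report's `outcomes` (status `FAIL`).
#' @param trace the trace the report was computed from.
#' @return a one-line diagnostic naming the requirement, the site, and the
#'   proximate evidence (error class, exit code or missing path).
#' @export
classify_failure <- function(outcome, trace) {
  stopifnot(identical(outcome$status, "FAIL"))
  reqs <- requirement_table()
  title <- reqs$title[reqs$code == outcome$requirement]
  site <- sprintf("%s, round %d", outcome$provider, outcome$round)
  evidence <- if (is.list(outcome$evidence) && length(outcome$evidence) == 1L && is.list(outcome$evidence[[1]])) {
    outcome$evidence[[1]]
  } else outcome$evidence
  extra <- switch(outcome$requirement,
    A = sprintf("connection evidence: %s", paste(unlist(evidence$kinds) %||% "none", collapse = ", ")),
    B = sprintf("error class %s", paste(unlist(evidence$error_classes) %||% "unknown", collapse = ", ")),
    C = "no prior result artifact at workspace start",
    D = {
      tail_txt <- paste(unlist(evidence$stderr_tail), collapse = " | ")
      sprintf("exit code %s%s", evidence$exit_code %||% "?",
              if (nzchar(tail_txt)) paste0("; stderr: ", tail_txt) else "")
    },
    E = sprintf("result artifact %s at %s", evidence$status %||% "absent", evidence$path %||% "?"),
    F = sprintf("aggregation failed: %s", outcome$detail),
    outcome$detail)
  sprintf("Requirement %s (%s) FAILED at %s: %s%s", outcome$requirement, title, site, extra,
          if (nzchar(outcome$detail) && outcome$requirement %in% c("A", "B")) paste0(" [", outcome$detail, "]") else "")
}

report_to_list <- function(report) {
  outs <- lapply(seq_len(nrow(report$outcomes)), function(i) {
    row <- report$outcomes[i, ]
    list(requirement = row$requirement, provider = row$provider, round = row$round,
         status = row$status, detail = row$detail, evidence = row$evidence[[1]])
  })
  list(config = report$config, verdict = report$verdict, outcomes = outs,
       diagnostics = as.list(report$diagnostics %||% character(0)), meta = report$meta)
}

#' Render a smoke-test report
#'
#' @param report an `fs_smoke_report`.
#' @param format `"json"` (round-trips through [report_from_json()]) or
#'   `"markdown"` (requirement x provider x round matrix).
#' @return a character scalar document.
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  if (!is_string(format[1]) || !format[1] %in% c("json", "markdown")) {
    fs_abort("unknown_format", sprintf("unknown report format '%s'", format[1]))
  }
  format <- format[1]
  if (format == "json") {
    return(as.character(toJSON(report_to_list(report), auto_unbox = TRUE, digits = NA,
                               null = "null", pretty = TRUE)))
  }
  o <- report$outcomes
  lines <- c(
    sprintf("# Smoke-test report: %s", report$verdict),
    "",
    sprintf("Paradigm %s, %d round(s), seed %d, %d synthetic record(s) per entity.",
            report$config$paradigm, report$config$rounds, report$config$seed,
            report$config$n_per_entity),
    "",
    "| Requirement | Provider | Round | Status | Detail |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %d | %s | %s |", o$requirement, o$provider, o$round, o$status,
            gsub("\\|", "/", o$detail)))
  if (length(report$diagnostics)) {
    lines <- c(lines, "", "## Diagnostics", "", paste0("- ", report$diagnostics))
  }
  paste(lines, collapse = "\n")
}

#' Parse a JSON report back into a report object
#' @param text JSON produced by [render_report()].
#' @return an `fs_smoke_report` structurally equal to the rendered one.
#' @export
report_from_json <- function(text) {
  x <- fromJSON(text, simplifyVector = FALSE)
  outcomes <- do.call(rbind, lapply(x$outcomes, function(o) {
    data.frame(requirement = o$requirement, provider = o$provider, round = o$round,
               status = o$status, detail = o$detail %||% "", stringsAsFactors = FALSE)
  }))
  outcomes$evidence <- lapply(x$outcomes, `[[`, "evidence")
  structure(list(config = x$config, outcomes = outcomes, verdict = x$verdict,
                 diagnostics = unlist(x$diagnostics) %||% character(0), meta = x$meta),
            class = "fs_smoke_report")
}

# canonical comparison form (timestamps excluded)
report_comparable <- function(report) {
  canonical_json(list(config = report$config[setdiff(names(report$config), "meta")],
                      verdict = report$verdict,
                      outcomes = lapply(seq_len(nrow(report$outcomes)), function(i) {
                        row <- report$outcomes[i, ]
                        list(requirement = row$requirement, provider = row$provider,
                             round = row$round, status = row$status)
                      })))
}

#' Compare two reports ignoring timestamps
#' @param a,b `fs_smoke_report` objects.
#' @return `TRUE` if verdicts and outcome matrices are identical.
#' @export
reports_equal <- function(a, b) identical(report_comparable(a), report_comparable(b))

#' Per-requirement aggregate of a report
#' @param report an `fs_smoke_report`.
#' @return named character vector requirement -> aggregate status (a
#'   requirement failing at any site fails overall).
#' @export
requirement_summary <- function(report) {
  out <- character(0)
  for (code in unique(report$outcomes$requirement)) {
    st <- report$outcomes$status[report$outcomes$requirement == code]
    out[[code]] <- if (any(st == "FAIL")) "FAIL"
                   else if (all(st == "SKIP")) "SKIP"
                   else if (any(st == "UNOBSERVED")) "UNOBSERVED"
                   else "PASS"
  }
  out
}

#' Process exit code for a report
#'
#' Contract: 0 = overall PASS, 2 = any requirement FAILed, 3 = a requirement
#' was UNOBSERVED under strict mode.
#' @param report an `fs_smoke_report`.
#' @return integer exit code.
#' @export
report_exit_code <- function(report) {
  switch(report$verdict, PASS = 0L, FAIL = 2L, UNOBSERVED = 3L, 4L)
}

#' @export
print.fs_smoke_report <- function(x, ...) {
  cat(sprintf("<fs_smoke_report> verdict: %s\n", x$verdict))
  print(requirement_summary(x))
  if (length(x$diagnostics)) cat(paste0("- ", x$diagnostics, collapse = "\n"), "\n")
  invisible(x)
}
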