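# Requirement evaluation over synthetic traces (no processes needed): the
# trace objects are assembled directly from step events.

make_trace <- function(events, paradigm = "IIL", strict = TRUE, order = c("p1", "p2")) {
  structure(list(
    config = simulation_config(paradigm, seed = 1, strict = strict, order = order),
    provider_order = order,
    events = fedsmoke:::events_frame(events),
    outcomes = list(), final_result = NULL, dataset_digests = list(),
    created = Sys.time()), class = "fs_trace")
}

healthy_events <- function(providers = c("p1", "p2"), round = 1L) {
  unlist(lapply(providers, function(p) {
    lapply(paste0("S", 1:5), function(s) fedsmoke:::step_event(round, p, s, "OK"))
  }), recursive = FALSE)
}

test_that("a healthy IIL trace passes all applicable criteria with no F outcomes", {
  report <- evaluate_trace(make_trace(healthy_events()))
  expect_equal(report$verdict, "PASS")
  expect_false("F" %in% report$outcomes$requirement)
  expect_equal(nrow(report$outcomes), 2 * 5)
  expect_equal(unname(requirement_summary(report)), rep("PASS", 5))
})

test_that("requirements map one-to-one onto steps and failures carry evidence", {
  evs <- healthy_events("p1")
  evs[[2]] <- fedsmoke:::step_event(1L, "p1", "S2", "FAIL", "relation \"patients\" does not exist",
                                    evidence = list(error_classes = list("UNKNOWN_RELATION")))
  evs[[3]]$status <- "SKIP"; evs[[4]]$status <- "SKIP"; evs[[5]]$status <- "SKIP"
  report <- evaluate_trace(make_trace(evs, order = "p1"))
  expect_equal(report$verdict, "FAIL")
  summ <- requirement_summary(report)
  expect_equal(summ[["B"]], "FAIL")
  expect_equal(summ[["A"]], "PASS")
  expect_equal(unname(summ[c("C", "D", "E")]), rep("SKIP", 3))
  expect_match(report$diagnostics, "Requirement B")
  expect_match(report$diagnostics, "UNKNOWN_RELATION")
  expect_match(report$diagnostics, "patients")
})

test_that("aggregation outcomes appear only under FL and drive requirement F", {
  evs <- c(healthy_events(), list(fedsmoke:::step_event(1L, "AGGREGATOR", "S6", "FAIL",
                                                        "aggregator exit 1, artifact absent")))
  report <- evaluate_trace(make_trace(evs, paradigm = "FL"))
  expect_equal(report$verdict, "FAIL")
  expect_equal(requirement_summary(report)[["F"]], "FAIL")
  expect_match(report$diagnostics, "Requirement F")
})

test_that("strict mode withholds PASS on unobserved criteria", {
  evs <- healthy_events("p1")
  evs[[1]]$status <- "UNOBSERVED"; evs[[2]]$status <- "UNOBSERVED"
  strict <- evaluate_trace(make_trace(evs, order = "p1", strict = TRUE))
  expect_equal(strict$verdict, "UNOBSERVED")
  expect_equal(report_exit_code(strict), 3L)
  lenient <- evaluate_trace(make_trace(evs, order = "p1", strict = FALSE))
  expect_equal(lenient$verdict, "PASS")
  expect_equal(report_exit_code(lenient), 0L)
})

test_that("JSON rendering round-trips and markdown covers every outcome", {
  report <- evaluate_trace(make_trace(healthy_events()))
  back <- report_from_json(render_report(report, "json"))
  expect_true(reports_equal(report, back))
  expect_identical(back$verdict, report$verdict)

  md <- render_report(report, "markdown")
  body_rows <- sum(grepl("^\\| [A-F] \\|", strsplit(md, "\n")[[1]]))
  expect_equal(body_rows, nrow(report$outcomes))

  expect_fs_error(render_report(report, "pdf"), "unknown_format")
})

test_that("classifier messages name the requirement, site and proximate cause", {
  evs <- healthy_events("p1")
  evs[[4]] <- fedsmoke:::step_event(1L, "p1", "S4", "FAIL", "exit code 1",
                                    evidence = list(exit_code = 1L,
                                                    stderr_tail = list("Error: boom")))
  evs[[5]]$status <- "SKIP"
  report <- evaluate_trace(make_trace(evs, order = "p1"))
  expect_match(report$diagnostics, "Requirement D")
  expect_match(report$diagnostics, "p1, round 1")
  expect_match(report$diagnostics, "boom")
})
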