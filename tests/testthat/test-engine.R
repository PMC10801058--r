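# Shared fixtures: a two-provider counting analysis exercised under all
# three paradigms. Heavier end-to-end properties live in test-acceptance.R.

counting_analysis <- c(
  'source("fs_client.R")',
  'src <- fs_source("db")',
  'if (!fs_connect(src)) quit(save = "no", status = 1)',
  'resp <- fs_query_sql(src, "SELECT COUNT(*) FROM items WHERE score >= 5")',
  'if (!isTRUE(resp$ok)) quit(save = "no", status = 1)',
  'n <- as.numeric(fs_agg_value(resp))',
  'prev <- if (identical(Sys.getenv("FS_PARADIGM"), "IIL")) fs_read_json(Sys.getenv("RESULT_PATH")) else NULL',
  'tot <- (if (is.null(prev)) 0 else as.numeric(prev$count)) + n',
  'fs_write_json(list(count = tot), Sys.getenv("RESULT_PATH"))')

counting_aggregator <- c(
  'library(jsonlite)',
  'files <- list.files(Sys.getenv("AGGREGATION_INPUT_DIR"), recursive = TRUE, full.names = TRUE)',
  'tot <- sum(vapply(files, function(f) as.numeric(fromJSON(f)$count), 0))',
  'path <- Sys.getenv("RESULT_PATH")',
  'dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)',
  'write_json(list(count = tot), path, auto_unbox = TRUE)')

two_schemas <- list(tiny_schema("prov_one"), tiny_schema("prov_two"))

oracle_count <- function(seed, n) {
  sum(vapply(two_schemas, function(s) {
    ds <- generate_dataset(s, n, derive_seed(seed, s$provider_id), reg_default)
    sum(vapply(ds$records$db$items, `[[`, 0, "score") >= 5)
  }, 0))
}

test_that("step mapping derives statuses from evidence and skips downstream of a failure", {
  pos <- list(round = 1L, provider = "p", initial = TRUE, prior_present = FALSE, external = FALSE)
  status_of <- function(evs) stats::setNames(vapply(evs, `[[`, "", "status"),
                                             vapply(evs, `[[`, "", "step"))

  healthy <- map_outcome_to_steps(fake_outcome(),
                                  fake_telemetry(c("CONNECT_OK", "QUERY_OK", "QUERY_OK")), pos)
  expect_equal(unname(status_of(healthy)), rep("OK", 5))

  schema_fail <- map_outcome_to_steps(fake_outcome(exit = 1L, result_status = "absent"),
                                      fake_telemetry(c("CONNECT_OK", "QUERY_FAIL"), c(NA, "UNKNOWN_RELATION")), pos)
  st <- status_of(schema_fail)
  expect_equal(unname(st[c("S1", "S2", "S3", "S4", "S5")]), c("OK", "FAIL", "SKIP", "SKIP", "SKIP"))

  conn_fail <- map_outcome_to_steps(fake_outcome(exit = 1L, result_status = "absent"),
                                    fake_telemetry("CONNECT_FAIL"), pos)
  expect_equal(unname(status_of(conn_fail)[1]), "FAIL")
  expect_equal(unname(status_of(conn_fail)[4]), "SKIP")

  # missing artifact with exit 0: S5 fails, S4 stays OK
  no_artifact <- map_outcome_to_steps(fake_outcome(result_status = "absent"),
                                      fake_telemetry(c("CONNECT_OK", "QUERY_OK")), pos)
  expect_equal(unname(status_of(no_artifact)[c("S4", "S5")]), c("OK", "FAIL"))

  # non-initial execution without prior results fails S3
  pos2 <- list(round = 2L, provider = "p", initial = FALSE, prior_present = FALSE, external = FALSE)
  no_state <- map_outcome_to_steps(fake_outcome(), fake_telemetry(c("CONNECT_OK", "QUERY_OK")), pos2)
  expect_equal(unname(status_of(no_state)["S3"]), "FAIL")

  # external proxy source: connection and query cannot be observed
  pos3 <- list(round = 1L, provider = "p", initial = TRUE, prior_present = FALSE, external = TRUE)
  ext <- map_outcome_to_steps(fake_outcome(), fake_telemetry(character(0)), pos3)
  expect_equal(unname(status_of(ext)[c("S1", "S2", "S4", "S5")]),
               c("UNOBSERVED", "UNOBSERVED", "OK", "OK"))
})

test_that("IIL carries state across hops and has rounds x providers executions", {
  pkg <- fixture_package(counting_analysis, counting_aggregator)
  config <- simulation_config("IIL", rounds = 2, seed = 21, n_per_entity = 12,
                              order = c("prov_one", "prov_two"))
  trace <- simulate(config, two_schemas, pkg, reg_default)
  expect_equal(trace_executions(trace), 2 * 2)
  expect_equal(nrow(trace$events), 2 * 2 * 5)
  expect_false(any(trace$events$step == "S6"))
  expect_true(all(trace$events$status == "OK"))
  # two full passes accumulate the count twice (round monotonicity)
  expect_equal(trace$final_result$parsed$count, 2 * oracle_count(21, 12))
})

test_that("FL aggregates replica results into the round's global result", {
  pkg <- fixture_package(counting_analysis, counting_aggregator)
  config <- simulation_config("FL", rounds = 2, seed = 22, n_per_entity = 12,
                              order = c("prov_one", "prov_two"))
  trace <- simulate(config, two_schemas, pkg, reg_default)
  expect_equal(trace_executions(trace), 2 * (2 + 1))
  s6 <- trace$events[trace$events$step == "S6", ]
  expect_equal(nrow(s6), 2)
  expect_true(all(s6$status == "OK"))
  expect_true(all(s6$provider == "AGGREGATOR"))
  expect_equal(trace$final_result$parsed$count, oracle_count(22, 12))
})

test_that("FL-INC never runs two replicas at once", {
  pkg <- fixture_package(counting_analysis, counting_aggregator)
  config <- simulation_config("FL_INC", rounds = 1, seed = 23, n_per_entity = 12,
                              order = c("prov_one", "prov_two"))
  trace <- simulate(config, two_schemas, pkg, reg_default)
  expect_equal(trace_max_concurrency(trace), 1L)
  expect_equal(trace$final_result$parsed$count, oracle_count(23, 12))
})

test_that("FL paradigms require an aggregator entrypoint", {
  no_agg <- fixture_package(counting_analysis)
  config <- simulation_config("FL", seed = 1, order = c("prov_one", "prov_two"))
  expect_fs_error(simulate(config, two_schemas, no_agg, reg_default), "config_invalid")
})

test_that("a failed hop terminates the IIL round and skips the rest", {
  crash <- fixture_package(c(
    'source("fs_client.R")',
    'src <- fs_source("db")',
    'if (!fs_connect(src)) quit(save = "no", status = 1)',
    'q <- fs_query_sql(src, "SELECT COUNT(*) FROM items")',
    'if (identical(Sys.getenv("FS_PROVIDER_ID"), "prov_one")) stop("boom")',
    'fs_write_json(list(count = 1), Sys.getenv("RESULT_PATH"))'))
  config <- simulation_config("IIL", seed = 3, n_per_entity = 5,
                              order = c("prov_one", "prov_two"))
  trace <- simulate(config, two_schemas, crash, reg_default)
  expect_equal(trace_executions(trace), 1)
  ev1 <- trace$events[trace$events$provider == "prov_one", ]
  expect_equal(ev1$status[ev1$step == "S4"], "FAIL")
  ev2 <- trace$events[trace$events$provider == "prov_two", ]
  expect_true(all(ev2$status == "SKIP"))
})

test_that("each execution sees exactly one provider's credentials", {
  spy <- fixture_package(c(
    'vars <- names(Sys.getenv())',
    'dir.create("state", showWarnings = FALSE)',
    'fault <- grep("_PASSWORD$|_USER$", vars, value = TRUE)',
    'writeLines(fault, "state/creds_seen.txt")',
    'writeLines(paste0("{\\"provider\\": \\"", Sys.getenv("FS_PROVIDER_ID"), "\\"}"), Sys.getenv("RESULT_PATH"))'))
  config <- simulation_config("IIL", seed = 8, n_per_entity = 3,
                              order = c("prov_one", "prov_two"))
  trace <- simulate(config, two_schemas, spy, reg_default)
  # the counting schema has one source ("db"): exactly one USER/PASSWORD pair
  for (o in trace$outcomes) {
    pwd_vars <- grep("_PASSWORD$", o$env_names, value = TRUE)
    expect_equal(pwd_vars, "DB_PASSWORD")
  }
})

test_that("an external-only simulation runs without any data generation", {
  p <- provisioned(tiny_schema("fixture"), n = 6, seed = 4)
  h <- p$handles$db
  ext <- attach_external_source("db", list(host = h$host, port = h$port,
                                           user = h$user, password = h$password),
                                provider_id = "sample_site")
  pkg <- fixture_package(counting_analysis, counting_aggregator)
  config <- simulation_config("IIL", seed = 1, order = "sample_site")
  trace <- simulate(config, list(), pkg, reg_default,
                    external_handles = list(sample_site = list(db = ext)))
  expect_length(trace$dataset_digests, 0)  # zero Data-Plugin invocations
  expect_equal(trace_executions(trace), 1)
  st <- trace$events$status[trace$events$step %in% c("S1", "S2")]
  expect_true(all(st == "UNOBSERVED"))
  expect_true(all(trace$events$status[trace$events$step %in% c("S4", "S5")] == "OK"))
})
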