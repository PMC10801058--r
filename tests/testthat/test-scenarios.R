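test_that("fault specs map each kind to its targeted requirement", {
  want <- c(WRONG_PORT = "A", BAD_CREDENTIALS = "A", SCHEMA_MISMATCH = "B",
            CRASH = "D", MISSING_RESULT = "E", AGGREGATOR_CRASH = "F")
  for (k in names(want)) expect_equal(fault_spec(k)$targeted_requirement, unname(want[[k]]))
  expect_fs_error(fault_spec("DISK_FULL"), "unknown_fault_kind")
})

test_that("scenario bundles are self-contained and reproducible on disk", {
  b <- make_user_study_scenario(seed = 2, n_per_provider = 10)
  expect_true(file.exists(b$schema_path))
  expect_true(file.exists(file.path(b$package_dir, "fedsmoke.yaml")))
  schemas <- parse_schema_document(readLines(b$schema_path))
  expect_setequal(vapply(schemas, `[[`, "", "provider_id"), c("hospital_a", "hospital_b"))
  ents <- unlist(lapply(schemas, function(s) vapply(s$sources[[1]]$entities, `[[`, "", "name")))
  expect_setequal(ents, c("patients", "patient_info"))
  # datasets regenerate deterministically for oracle computation
  d1 <- scenario_datasets(b); d2 <- scenario_datasets(b)
  expect_identical(vapply(d1, dataset_digest, ""), vapply(d2, dataset_digest, ""))
})

test_that("age range forced below the predicate threshold yields a zero count", {
  b <- make_user_study_scenario(seed = 6, n_per_provider = 25)
  ttl <- readLines(b$schema_path)
  ttl <- gsub("fs:genMax 100", "fs:genMax 49", ttl)
  writeLines(ttl, b$schema_path)
  expect_equal(b$oracle(scenario_datasets(b)), 0)
})

test_that("fault injection rejects paradigm-inapplicable faults", {
  iil <- make_user_study_scenario(seed = 1, paradigm = "IIL")
  expect_fs_error(inject_fault(iil, "AGGREGATOR_CRASH"), "fault_not_applicable")
  expect_fs_error(inject_fault(make_tabular_scenario(seed = 1, n_providers = 2, n_rows = 5),
                               "SCHEMA_MISMATCH"), "fault_not_applicable")
})

test_that("fault injection leaves the original bundle untouched", {
  b <- make_user_study_scenario(seed = 1)
  fb <- inject_fault(b, "CRASH")
  expect_null(b$fault)
  expect_equal(fb$fault$kind, "CRASH")
  expect_equal(fb$expected$requirement, "D")
  m0 <- yaml::read_yaml(file.path(b$package_dir, "fedsmoke.yaml"))
  m1 <- yaml::read_yaml(file.path(fb$package_dir, "fedsmoke.yaml"))
  expect_null(m0$env$FS_FAULT)
  expect_equal(m1$env$FS_FAULT, "CRASH")
})

test_that("emit_scenario writes a runnable bundle for the CLI", {
  out <- tempfile("emit-")
  b <- emit_scenario("tabular", out, seed = 4)
  expect_equal(b$name, "tabular")
  expect_true(file.exists(file.path(out, "schema.ttl")))
  expect_true(file.exists(file.path(out, "config.yaml")))
  schemas <- parse_schema_document(readLines(file.path(out, "schema.ttl")))
  expect_length(schemas, 6)  # six tabular providers by default
  expect_fs_error(emit_scenario("nope", tempfile()), "config_invalid")
})
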