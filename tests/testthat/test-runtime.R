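test_that("manifest loading validates its contract", {
  expect_fs_error(load_package(tempfile("missing-")), "manifest_missing")

  d <- tempfile(); dir.create(d)
  expect_fs_error(load_package(d), "manifest_missing")
  yaml::write_yaml(list(result_path = "state/results.json"), file.path(d, "fedsmoke.yaml"))
  expect_fs_error(load_package(d), "manifest_invalid")
  yaml::write_yaml(list(entrypoint = list("Rscript", "analysis.R")), file.path(d, "fedsmoke.yaml"))
  expect_fs_error(load_package(d), "entrypoint_missing")
  writeLines("cat(1)", file.path(d, "analysis.R"))
  expect_s3_class(load_package(d), "fs_analysis_package")

  yaml::write_yaml(list(entrypoint = list("Rscript", "analysis.R"),
                        result_path = "../outside.json"), file.path(d, "fedsmoke.yaml"))
  expect_fs_error(load_package(d), "manifest_invalid")
})

test_that("workspace overlay reproduces carried state byte-identically", {
  pkg <- fixture_package(c(
    'dir.create("state", showWarnings = FALSE)',
    'writeLines(c("{\\"count\\": 7}"), Sys.getenv("RESULT_PATH"))',
    'writeLines("aux", "state/aux.txt")'))
  ws1 <- prepare_workspace(pkg)
  expect_false(dir.exists(file.path(ws1, "state")))
  out1 <- execute_step(ws1, c(), pkg$manifest, timeout = 60)
  expect_equal(out1$exit_code, 0)
  expect_equal(out1$result$parsed$count, 7)

  state <- out1$workspace_state
  ws2 <- prepare_workspace(pkg, state)
  ws3 <- prepare_workspace(pkg, state)
  expect_true(file.exists(file.path(ws2, "state", "results.json")))
  # state subtree at the start of the next execution matches the snapshot
  expect_identical(md5_tree(file.path(ws2, "state")), state$digest)
  expect_identical(md5_tree(ws2), md5_tree(ws3))

  # a corrupted snapshot is refused
  writeLines("tampered", file.path(state$dir, "results.json"))
  expect_fs_error(prepare_workspace(pkg, state), "state_corrupt")
})

test_that("executions capture exit codes, crashes and timeouts without raising", {
  crash <- fixture_package('stop("deliberate failure")')
  out <- execute_step(prepare_workspace(crash), c(), crash$manifest, timeout = 60)
  expect_gt(out$exit_code, 0)
  expect_match(out$stderr, "deliberate failure")

  slow <- fixture_package('Sys.sleep(30)')
  out <- execute_step(prepare_workspace(slow), c(), slow$manifest, timeout = 2)
  expect_equal(out$exit_code, 124)
  expect_true(out$timed_out)
})

test_that("children see only baseline, injected and interpreter variables", {
  pkg <- fixture_package(c(
    'vars <- names(Sys.getenv())',
    'dir.create("state", showWarnings = FALSE)',
    'writeLines(vars, "state/env.txt")',
    'writeLines("{}", Sys.getenv("RESULT_PATH"))'))
  out <- execute_step(prepare_workspace(pkg), c(MYDB_HOST = "127.0.0.1", MYDB_PORT = "99"),
                      pkg$manifest, timeout = 60)
  seen <- readLines(file.path(out$workspace, "state", "env.txt"))
  # injected variables arrive ...
  expect_true(all(c("MYDB_HOST", "MYDB_PORT", "RESULT_PATH") %in% seen))
  # ... and nothing except baseline + R's own runtime variables leaks in
  leaked <- setdiff(seen, c("MYDB_HOST", "MYDB_PORT", fedsmoke:::baseline_env_names()))
  expect_true(all(grepl("^R_|^_R_|^PWD$|^SHLVL$|^LN_S$|^MAKE$|^PAGER$|^TAR$|^SED$|^EDITOR$|^R_BROWSER$", leaked)),
              info = paste(leaked, collapse = ", "))
})

test_that("result collection reports presence, absence and corruption", {
  ok <- fixture_package('dir.create("state", showWarnings = FALSE); writeLines("{\\"v\\": 1}", Sys.getenv("RESULT_PATH"))')
  out <- execute_step(prepare_workspace(ok), c(), ok$manifest, timeout = 60)
  expect_equal(collect_result(out, ok$manifest)$status, "ok")

  none <- fixture_package('invisible(NULL)')
  out <- execute_step(prepare_workspace(none), c(), none$manifest, timeout = 60)
  expect_equal(collect_result(out, none$manifest)$status, "absent")

  bad <- fixture_package('dir.create("state", showWarnings = FALSE); writeLines("{not json", Sys.getenv("RESULT_PATH"))')
  out <- execute_step(prepare_workspace(bad), c(), bad$manifest, timeout = 60)
  expect_equal(collect_result(out, bad$manifest)$status, "corrupt")
})

test_that("a failing setup command aborts workspace preparation", {
  d <- tempfile(); dir.create(d)
  writeLines("cat(1)", file.path(d, "analysis.R"))
  yaml::write_yaml(list(entrypoint = list("Rscript", "analysis.R"),
                        setup = list("sh", "-c", "exit 3")), file.path(d, "fedsmoke.yaml"))
  pkg <- load_package(d)
  expect_fs_error(prepare_workspace(pkg, run_setup = TRUE), "setup_failed")
})
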