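test_that("registration is injective and resolution is total over the vocabulary", {
  reg <- plugin_registry()
  pl <- data_type_plugin(fs_iri("integer"), function(p, s) 1L)
  register_plugin(reg, pl)
  expect_identical(resolve_plugin(reg, fs_iri("integer")), pl)
  expect_fs_error(register_plugin(reg, data_type_plugin(fs_iri("integer"), function(p, s) 2L)),
                  "duplicate_binding")
  expect_fs_error(resolve_plugin(reg, fs_iri("nope")), "unresolved_iri")

  # every atomic-type IRI declared in the shipped vocabulary resolves
  vocab <- turtle_parse(paste(readLines(fs_vocabulary_path()), collapse = "\n"))
  atomic <- vocab$subject[vocab$object == fs_iri("AtomicType")]
  tech <- vocab$subject[vocab$object == fs_iri("SourceTechnology")]
  expect_length(atomic, 12)
  for (iri in c(atomic, tech)) expect_s3_class(resolve_plugin(reg_default, iri), "fs_plugin")
  # resolution is stable (same object on repeated calls)
  expect_identical(resolve_plugin(reg_default, fs_iri("double")),
                   resolve_plugin(reg_default, fs_iri("double")))
})

test_that("generated values honour each plugin's type contract", {
  stream <- random_stream(9L)
  int_pl <- resolve_plugin(reg_default, fs_iri("integer"))
  expect_equal(generate_value(int_pl, list(min = 5, max = 5), stream), 5L)
  expect_fs_error(generate_value(int_pl, list(min = 9, max = 1), stream), "invalid_params")

  pat <- generate_value(resolve_plugin(reg_default, fs_iri("fhir-Patient")), list(), stream)
  expect_identical(pat$resourceType, "Patient")
  expect_true(nzchar(pat$id))

  jpg <- generate_value(resolve_plugin(reg_default, fs_iri("jpeg")),
                        list(width = 16, height = 16), stream)
  expect_identical(jpg[1:2], as.raw(c(0xFF, 0xD8)))

  # each built-in generator satisfies its own checker over many draws
  for (iri in registered_iris(reg_default)) {
    pl <- resolve_plugin(reg_default, iri)
    if (!inherits(pl, "fs_data_plugin")) next
    params <- if (grepl("jpeg", iri)) list(width = 8, height = 8) else list()
    for (i in 1:20) expect_true(pl$check(generate_value(pl, params, stream), params))
  }
})

test_that("value generation is deterministic given the stream seed", {
  for (iri in c(fs_iri("double"), fs_iri("uuid"), fs_iri("date"))) {
    pl <- resolve_plugin(reg_default, iri)
    v1 <- generate_value(pl, list(), random_stream(123L))
    v2 <- generate_value(pl, list(), random_stream(123L))
    expect_identical(v1, v2)
  }
})

test_that("streams leave the session's global random state untouched", {
  set.seed(555)
  expected <- runif(3)
  set.seed(555)
  s <- random_stream(1L)
  invisible(rs_unif(s, n = 10))
  expect_identical(runif(3), expected)
})
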