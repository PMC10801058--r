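test_that("constructors enforce structural invariants", {
  expect_fs_error(attribute_spec("age", "not an iri"), "invalid_schema")
  expect_fs_error(attribute_spec("bad name", fs_iri("integer")), "invalid_schema")
  expect_fs_error(attribute_spec("p", fs_iri("double"), list(min = 5, max = 1)), "invalid_params")
  expect_fs_error(attribute_spec("p", fs_iri("double"), list(null_prob = 1.5)), "invalid_params")
  expect_fs_error(entity_spec("empty", list()), "invalid_schema")
  a <- attribute_spec("age", fs_iri("integer"))
  expect_fs_error(entity_spec("dup", list(a, a)), "invalid_schema")
})

test_that("schema documents round-trip through Turtle", {
  # fixed seed drives a small family of randomized schemas
  stream <- random_stream(401L)
  for (rep in 1:5) {
    schemas <- lapply(1:3, function(i) random_schema(stream, sprintf("prov_%d_%d", rep, i)))
    ttl <- serialize_provider_schemas(schemas)
    expect_true(schemas_equal(schemas, parse_schema_document(ttl)))
    expect_identical(ttl, serialize_provider_schemas(parse_schema_document(ttl)))
  }
})

test_that("link arcs survive the round-trip and dangling links are rejected", {
  schema <- provider_schema("p1", list(
    data_source_spec("store", fs_iri("objectstore"), list(
      entity_spec("images", list(attribute_spec("content", fs_iri("jpeg")))))),
    data_source_spec("srv", fs_iri("fhir"), list(
      entity_spec("Media", list(
        attribute_spec("resource", fs_iri("fhir-Media")),
        attribute_spec("image", fs_iri("uuid"),
                       links_to = list(source = "store", entity = "images"))))))))
  back <- parse_schema_document(serialize_provider_schemas(list(schema)))
  expect_true(schemas_equal(list(schema), back))

  broken <- gsub("p1/store/images>", "p1/store/missing>",
                 serialize_provider_schemas(list(schema)), fixed = TRUE)
  expect_fs_error(parse_schema_document(broken), "dangling_link")
})

test_that("documents without provider nodes are rejected", {
  expect_fs_error(parse_schema_document("@prefix fs: <http://fedsmoke.org/vocab#> ."),
                  "no_provider_found")
  expect_fs_error(parse_schema_document(
    "@prefix ex: <http://example.org/> .\nex:a ex:b ex:c ."), "no_provider_found")
})

test_that("validation resolves every IRI and is sound on planted faults", {
  expect_equal(nrow(validate_provider_schema(tiny_schema(), reg_default)), 0)

  # k planted unresolved type IRIs yield exactly k unresolved-IRI diagnostics
  stream <- random_stream(77L)
  for (k in 1:3) {
    attrs <- lapply(1:4, function(i) attribute_spec(sprintf("a%d", i), fs_iri("integer")))
    for (j in seq_len(k)) {
      attrs[[j]] <- attribute_spec(sprintf("a%d", j), sprintf("http://example.org/unknown-%d", j))
    }
    schema <- provider_schema("p", list(
      data_source_spec("db", fs_iri("relational"), list(entity_spec("e", attrs)))))
    diags <- validate_provider_schema(schema, reg_default)
    expect_equal(sum(diags$code == "unresolved_type_iri"), k)
  }

  # empty registry: the technology IRI cannot resolve either
  diags <- validate_provider_schema(tiny_schema(), plugin_registry())
  expect_true(any(diags$code == "unresolved_technology_iri"))
  expect_true(all(c("severity", "path", "code", "message") %in% names(diags)))
})

test_that("empty schema list serializes to prefix declarations only", {
  ttl <- serialize_provider_schemas(list())
  lines <- strsplit(ttl, "\n")[[1]]
  expect_true(all(grepl("^@prefix|^$", lines)))
})
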