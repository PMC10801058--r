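test_that("datasets have the requested cardinality and are seed-deterministic", {
  schema <- tiny_schema()
  d1 <- generate_dataset(schema, 15, 42, reg_default)
  expect_true(all(dataset_counts(d1) == 15))
  d2 <- generate_dataset(schema, 15, 42, reg_default)
  expect_identical(dataset_digest(d1), dataset_digest(d2))
  d3 <- generate_dataset(schema, 15, 43, reg_default)
  expect_false(identical(dataset_digest(d1), dataset_digest(d3)))

  expect_fs_error(generate_dataset(schema, 0, 1, reg_default), "invalid_params")
})

test_that("every generated value passes the type checker of its attribute's IRI", {
  stream <- random_stream(8L)
  for (rep in 1:3) {
    schema <- random_schema(stream, sprintf("conf_%d", rep))
    ds <- generate_dataset(schema, 5, 100 + rep, reg_default)
    for (src in schema$sources) for (ent in src$entities) for (at in ent$attributes) {
      pl <- resolve_plugin(reg_default, at$type_iri)
      for (rec in ds$records[[src$name]][[ent$name]]) {
        expect_true(pl$check(rec[[at$name]], at$params))
      }
    }
  }
})

test_that("link attributes reference existing records and FHIR wiring resolves", {
  schema <- provider_schema("clinic", list(
    data_source_spec("imagestore", fs_iri("objectstore"), list(
      entity_spec("images", list(attribute_spec("content", fs_iri("jpeg"),
                                                list(width = 8, height = 8)))))),
    data_source_spec("fhirstore", fs_iri("fhir"), list(
      entity_spec("Patient", list(attribute_spec("resource", fs_iri("fhir-Patient")))),
      entity_spec("Media", list(
        attribute_spec("resource", fs_iri("fhir-Media")),
        attribute_spec("patient", fs_iri("uuid"),
                       links_to = list(source = "fhirstore", entity = "Patient")),
        attribute_spec("image", fs_iri("uuid"),
                       links_to = list(source = "imagestore", entity = "images"))))))))
  ds <- generate_dataset(schema, 10, 5, reg_default)
  patient_ids <- vapply(ds$records$fhirstore$Patient, `[[`, "", "_id")
  image_ids <- vapply(ds$records$imagestore$images, `[[`, "", "_id")
  for (m in ds$records$fhirstore$Media) {
    expect_true(m$patient %in% patient_ids)
    expect_true(m$image %in% image_ids)
    expect_identical(m$resource$subject$reference, paste0("Patient/", m$patient))
    key <- sub("^objects/", "", m$resource$content$url)
    expect_true(key %in% names(ds$blobs))
  }
  expect_length(ds$blobs, 10)
  expect_true(all(vapply(ds$blobs, function(b) identical(b[1:2], as.raw(c(0xFF, 0xD8))), TRUE)))
})

test_that("null probability produces missing values at roughly the configured rate", {
  schema <- provider_schema("p", list(
    data_source_spec("db", fs_iri("relational"), list(
      entity_spec("e", list(
        attribute_spec("always", fs_iri("integer")),
        attribute_spec("half", fs_iri("integer"), list(null_prob = 0.5))))))))
  ds <- generate_dataset(schema, 200, 7, reg_default)
  nulls <- sum(vapply(ds$records$db$e, function(r) is.null(r$half), TRUE))
  expect_gt(nulls, 50)
  expect_lt(nulls, 150)
  expect_true(all(!vapply(ds$records$db$e, function(r) is.null(r$always), TRUE)))
})

test_that("datasets dump to plain-text files for inspection", {
  dir <- tempfile()
  dump_dataset(generate_dataset(tiny_schema(), 5, 1, reg_default), dir)
  csv <- utils::read.csv(file.path(dir, "db", "items.csv"))
  expect_equal(nrow(csv), 5)
  expect_true(all(c("X_id", "item_id", "score", "grp") %in% names(csv)) ||
              all(c("item_id", "score", "grp") %in% names(csv)))
})
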