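test_that("provisioned sources serve the full dataset and classify errors", {
  p <- provisioned(tiny_schema(), n = 20, seed = 5)
  h <- p$handles$db

  expect_true(isTRUE(gateway_query(h, request = list(op = "ping"))$ok))
  res <- gateway_query(h, request = list(op = "query", sql = "SELECT COUNT(*) FROM items"))
  expect_equal(res$rows[[1]][[1]], 20)

  # oracle equivalence over a small aggregate family
  scores <- vapply(p$dataset$records$db$items, `[[`, 0, "score")
  for (cs in list(c("SELECT COUNT(*) FROM items WHERE score >= 5", sum(scores >= 5)),
                  c("SELECT SUM(score) FROM items", sum(scores)),
                  c("SELECT AVG(score) FROM items WHERE score < 8", mean(scores[scores < 8])))) {
    res <- gateway_query(h, request = list(op = "query", sql = cs[[1]]))
    expect_equal(res$rows[[1]][[1]], as.numeric(cs[[2]]), tolerance = 1e-9)
  }

  bad <- gateway_query(h, request = list(op = "query", sql = "SELECT COUNT(*) FROM wrong_table"))
  expect_false(isTRUE(bad$ok))
  expect_equal(bad$error_class, "UNKNOWN_RELATION")

  auth <- gateway_query(h, credentials = list(user = h$user, password = "nope"),
                        request = list(op = "ping"))
  expect_false(isTRUE(auth$ok))

  tel <- source_telemetry(h)
  # exactly one telemetry event per gateway interaction
  expect_equal(nrow(tel), 7)
  expect_equal(tel$kind[1], "CONNECT_OK")
  expect_true("AUTH_FAIL" %in% tel$kind)
  expect_equal(tel$error_class[tel$kind == "QUERY_FAIL"], "UNKNOWN_RELATION")
})

test_that("providers are isolated: disjoint ports and credentials", {
  pa <- provisioned(tiny_schema("prov_a"), n = 5, seed = 9)
  pb <- provisioned(tiny_schema("prov_b"), n = 5, seed = 9)
  ha <- pa$handles$db; hb <- pb$handles$db
  expect_false(ha$port == hb$port)
  creds_a <- c(ha$user, ha$password)
  creds_b <- c(hb$user, hb$password)
  expect_length(intersect(creds_a, creds_b), 0)
  # credentials of provider a are rejected at provider b
  r <- gateway_query(hb, credentials = list(user = ha$user, password = ha$password),
                     request = list(op = "ping"))
  expect_false(isTRUE(r$ok))
})

test_that("teardown is idempotent, rejects later queries, retains telemetry", {
  p <- provisioned(tiny_schema(), n = 3, seed = 2)
  h <- p$handles$db
  invisible(gateway_query(h, request = list(op = "ping")))
  n_before <- nrow(source_telemetry(h))
  teardown_provider(p$handles)
  expect_false(h$live)
  expect_equal(nrow(source_telemetry(h)), n_before)
  teardown_provider(p$handles)  # no error on repeat

  r <- gateway_query(h, request = list(op = "ping"))
  expect_false(isTRUE(r$ok))
  tel <- source_telemetry(h)
  expect_equal(tel$kind[nrow(tel)], "CONNECT_FAIL")

  # the port is reusable by the next provision (same seed -> same port)
  p2 <- provisioned(tiny_schema(), n = 3, seed = 2)
  expect_equal(p2$handles$db$port, h$port)
})

test_that("object store and FHIR-like backends serve their content", {
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
  p <- provisioned(schema, n = 4, seed = 11)

  meta <- gateway_query(p$handles$fhirstore, request = list(op = "fhir_meta"))
  expect_setequal(unlist(meta$resourceTypes), c("Patient", "Media"))
  media <- gateway_query(p$handles$fhirstore, request = list(op = "fhir_list", type = "Media"))
  expect_length(media$resources, 4)
  one <- media$resources[[1]]
  got <- gateway_query(p$handles$fhirstore, request = list(op = "fhir_get", type = "Media", id = one$id))
  expect_identical(got$resource$id, one$id)
  missing_type <- gateway_query(p$handles$fhirstore, request = list(op = "fhir_list", type = "Observation"))
  expect_equal(missing_type$error_class, "UNKNOWN_RELATION")

  key <- sub("^objects/", "", one$content$url)
  blob <- gateway_query(p$handles$imagestore, request = list(op = "object_get", key = key))
  expect_true(isTRUE(blob$ok))
  bytes <- jsonlite::base64_dec(blob$b64)
  expect_identical(bytes[1:2], as.raw(c(0xFF, 0xD8)))
  expect_equal(gateway_query(p$handles$imagestore,
                             request = list(op = "object_get", key = "nope.jpg"))$error_class,
               "NOT_FOUND")
})

test_that("external sources attach, forward queries, and report unreachable endpoints", {
  # fixture server: a provisioned source standing in for a pre-existing one
  p <- provisioned(tiny_schema("fixture"), n = 6, seed = 4)
  h <- p$handles$db
  ext <- attach_external_source("sampledb", list(host = h$host, port = h$port,
                                                 user = h$user, password = h$password))
  expect_true(ext$external)
  res <- gateway_query(ext, request = list(op = "query", sql = "SELECT COUNT(*) FROM items"))
  expect_equal(res$rows[[1]][[1]], 6)

  expect_fs_error(attach_external_source("dead", list(host = "127.0.0.1", port = 1)),
                  "endpoint_unreachable")
})
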