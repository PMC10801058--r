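Package: fedsmoke
Title: Smoke Testing of Distributed Analytics Code by Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-provider distributed-analytics (DA) executions on
    schema-driven synthetic data sources so that analysis code can be smoke
    tested before it is deployed to real data holders. Provider data sources
    are described in an RDF/Turtle schema vocabulary, instantiated as isolated
    loopback gateway servers populated with seeded synthetic data, and analysis
    packages are executed against them as sandboxed child processes under the
    Institutional Incremental Learning (IIL) or Federated Learning (FL / FL-INC)
    paradigm. The resulting execution trace is validated against six
    operability requirements (A-F: connection, schema match, previous-result
    loading, error-free execution, result storage, aggregation), yielding a
    per-requirement smoke-test report with evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    jpeg,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
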