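# fedsmoke

Smoke testing of distributed-analytics (DA) code by simulation.

## The problem

In distributed analytics the analysis code travels to decentralized data
holders (hospitals, registries) and only intermediate results are shared.
That makes testing hard: a misconfigured port, a table that is called
`patients` at one site and `patient_info` at another, or a result file
written to the wrong path will abort the real distributed run -- and every
such defect costs a full redeployment round across multiple institutions.

fedsmoke lets developers of DA analyses run a **smoke test** -- a shallow,
fast, automated operability check -- entirely locally, before deployment:

1. each data provider is described in an RDF/Turtle **schema document**
   (source technology, entities, attribute types, link arcs, all keyed by
   IRIs);
2. a **plugin registry** maps those IRIs to Database Plugins (which
   provision embedded relational / document / object-store / FHIR-like
   sources as isolated loopback servers) and Data Plugins (which generate
   seeded synthetic values: integers, dates, UUIDs, JPEGs, FHIR
   resources);
3. the **simulation engine** executes the user's analysis package as
   sandboxed child processes against those sources under IIL (sequential,
   state carried hop to hop), FL (parallel replicas + aggregator) or
   FL-INC (at most one replica at a time);
4. the execution trace is evaluated against six requirements, one per
   workflow step:

   | | Requirement | Step |
   |---|---|---|
   | A | proper connection interface | S1 connect |
   | B | matching data schema | S2 query |
   | C | previous results loaded / initialized | S3 load |
   | D | analysis executes without errors | S4 analyze |
   | E | result stored at the agreed path/format | S5 store |
   | F | aggregation succeeds (FL paradigms) | S6 aggregate |

The result is a smoke-test report with per-requirement, per-provider,
per-round verdicts and evidence (gateway telemetry, exit codes, artifact
digests). Synthetic records are placeholders for operability testing only
-- deliberately not statistically plausible data.

## Worked example

The two-hospital counting study: both hospitals offer a relational source,
but the patient relation is named `patients` at Hospital A and
`patient_info` at Hospital B. The bundled reference analysis maps the
relation per provider and counts patients aged at least 50:

```r
library(fedsmoke)

bundle <- make_user_study_scenario(seed = 42)   # 50 synthetic patients/hospital
res <- run_scenario(bundle)
res$report
#> <fs_smoke_report> verdict: PASS
#>      A      B      C      D      E
#> "PASS" "PASS" "PASS" "PASS" "PASS"
res$result$count
#> [1] 52
bundle$oracle(scenario_datasets(bundle))        # brute-force count over the records
#> [1] 52
```

The smoke test passes and the simulated IIL execution reproduces the
in-memory oracle count (52 of the 100 generated patients are >= 50 at this
seed). Now the classic planted error -- an analysis that naively queries
`patients` at both hospitals:

```r
naive <- inject_fault(bundle, "SCHEMA_MISMATCH")
run_scenario(naive)$report
#> <fs_smoke_report> verdict: FAIL
#>      A      B      C      D      E
#> "PASS" "FAIL" "PASS" "PASS" "PASS"
#> - Requirement B (Matching schema) FAILED at hospital_b, round 1:
#>   error class UNKNOWN_RELATION [relation "patients" does not exist]
```

Exactly Requirement B fails, at exactly the mismatched provider, with the
offending relation named. Five further canonical faults (`WRONG_PORT`,
`BAD_CREDENTIALS`, `CRASH`, `MISSING_RESULT`, `AGGREGATOR_CRASH`) target
requirements A, A, D, E and F the same way.

Other entry points: `make_imaging_scenario()` (FHIR-like server + object
store of synthetic JPEGs per provider), `make_tabular_scenario()` (six
sites, pooled-statistics analysis), `simulate()` / `evaluate_trace()` /
`render_report()` for custom schemas and packages, and a command-line
interface:

```sh
inst/cli/fedsmoke scenario emit user_study --out demo
inst/cli/fedsmoke smoke --schema demo/schema.ttl --package demo/package --out demo-report
inst/cli/fedsmoke schema validate demo/schema.ttl
```

Exit codes: 0 overall PASS, 2 any requirement failed, 3 a requirement was
unobserved under strict mode, 4 configuration error.

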