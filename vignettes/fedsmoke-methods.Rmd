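---
title: "Smoke testing distributed analytics by simulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoke testing distributed analytics by simulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Distributed analytics (DA) executes analysis code *at* decentralized data
holders -- hospitals, registries, biobanks -- and shares only intermediate
results (aggregates, model updates), never raw records. Two execution
paradigms dominate: institutional incremental learning (IIL), where the
analysis travels from provider to provider accumulating results, and
federated learning (FL), where replicas run at all providers in parallel and
a central aggregator merges their outputs each round (FL-INC is FL with at
most one replica running at a time).

The distributed setting makes ordinary trial-and-error development
expensive: any defect -- a wrong port, a table name that differs at one
site, a result file written to the wrong path -- surfaces only after the
code has been shipped to real data holders, and fixing it costs another full
deployment round. A *smoke test* is the cheap counterpart: a shallow, fast,
automated initial run that checks basic operability before anything deeper.
fedsmoke performs that smoke test locally by **simulating the entire DA
execution** on synthetic stand-ins for the real data sources.

## Workflow steps and requirements

Every DA execution, regardless of infrastructure, performs six abstract
steps per round: connect to the data source (S1), query the data (S2), load
previous intermediate results or initialize (S3), run the analysis (S4),
store the updated results (S5), and -- in aggregation paradigms -- combine
the replica results into a global result (S6). Each step has a matching
operability requirement:

| Requirement | Step | What must hold |
|---|---|---|
| A | S1 | all connection parameters (host, port, credentials, source type) are correct |
| B | S2 | the schema the code expects matches the schema the source serves |
| C | S3 | previous results are found and loaded; the first round initializes |
| D | S4 | the analysis process exits without error (exit code 0) |
| E | S5 | the result artifact appears at the agreed path in the agreed format |
| F | S6 | aggregation terminates without error and stores a global result |

A simulation produces an execution trace of step events; the report module
turns those into per-requirement, per-provider, per-round verdicts
(`PASS`/`FAIL`/`SKIP`/`UNOBSERVED`). A requirement that fails anywhere fails
overall; per-site detail is retained. Deliberately, **no plausibility
checking** of analysis results is attempted -- that would contradict the
shallow-and-fast character of a smoke test.

## Architecture

### Schema model

Provider data sources are modeled in RDF, serialized as Turtle, under a
single versioned vocabulary (`http://fedsmoke.org/vocab#`): a `Provider`
has `DataSource`s, a source has `Entity`s (tables, collections, resource
types), an entity has typed `Attribute`s. Two IRI families act as dispatch
keys: *technology IRIs* (`fs:relational`, `fs:document`, `fs:objectstore`,
`fs:fhir`) bind a source to the Database Plugin that provisions it, and
*atomic-type IRIs* (`fs:integer`, `fs:double`, ..., `fs:jpeg`,
`fs:fhir-Patient`) bind each attribute to the Data Plugin that generates its
values -- exactly one plugin per IRI, enforced by the registry. `fs:linksTo`
arcs express foreign-key-like references between entities of the same
provider, including across sources (a FHIR-like server referencing an
object store). Declaration order is made explicit with `fs:index` literals
so that parse ∘ serialize is the identity on structural content and
repeated serialization is byte-identical. OWL reasoning is deliberately not
performed; the vocabulary is used as a plain RDF schema.

The Turtle reader/writer implements the subset of Turtle this vocabulary
needs (prefixes, predicate-object lists, string/number/boolean literals,
`^^` datatypes); the test suite cross-checks it against an independent RDF
library, which must agree on the triple count and reproduce the identical
structure from its own re-serialization.

### Synthetic data generation

`generate_dataset()` produces `n` records per entity from one root seed.
Each (provider, source, entity) derives its own random stream by hashing
the identifiers into the seed, so values never depend on generation order
or on sibling entities. Link attributes are filled with identifiers of
already-generated target records (entities are generated in
link-dependency order); JPEG attributes produce seeded noise images
(default 64x64) whose bytes land in the dataset's blob store; FHIR-typed
attributes produce minimal resource skeletons that are then wired to their
link targets (`subject.reference = "Patient/<id>"`, `content.url =
"objects/<key>"`). The generator emulates *structure*, not statistics: the
records are placeholders that can be queried and processed, intentionally
not plausible clinical data. Passing smoke tests therefore demonstrates
operability of the analysis code against the modeled schema -- they say
nothing about analytical validity on real data, and a schema that was
re-modeled incorrectly will not be caught here.

### Source fabric and gateway

Each source is provisioned as its own background R process serving a
loopback TCP port -- one process per source, one port per source, one
credential pair per provider, so the isolation the criteria depend on
(disjoint ports and credentials between providers) holds physically, not
by convention. The wire protocol is one JSON object per line in each
direction; endpoints map to request ops (`ping`, `query` for SQL,
`docquery` for filter documents, `fhir_meta`/`fhir_list`/`fhir_get`,
`object_get`/`object_list`). The gateway authenticates before executing,
never crashes on a malformed request, and appends exactly one telemetry
event per request (`CONNECT_OK`, `AUTH_FAIL`, `QUERY_OK`, `QUERY_FAIL` with
an error class). This telemetry is what makes Requirements A and B
mechanically observable:

* connection-level failures (refused connection, authentication) map to A;
* schema-level failures (`UNKNOWN_RELATION`, `UNKNOWN_ATTRIBUTE`,
  `TYPE_MISMATCH`, `SYNTAX`, `NOT_FOUND`) map to B.

A connection that never reaches a server (wrong port, torn-down source)
cannot be logged server-side; the client half of the gateway records
`CONNECT_FAIL` instead, and the engine merges both sides. Already-running
external sources can be attached by endpoint; since their internals are
not introspected, their S1/S2 evidence is reported `UNOBSERVED` rather than
silently vouched for.

The embedded relational backend executes a small documented SQL subset
(`SELECT` items or `COUNT/SUM/AVG/MIN/MAX` aggregates, one `WHERE`
predicate, case-insensitive keywords) over the in-memory records. That
subset covers the reference analyses and the oracle family the tests
compare against; anything outside it is a `SYNTAX` error, which is the
honest smoke-test answer for an unsupported dialect feature.

### Analysis runtime

An analysis package is a directory of user code plus a `fedsmoke.yaml`
manifest (entrypoint command, optional setup and aggregator commands,
result path, static environment). Executions run as child processes with a
**scrubbed environment**: baseline interpreter variables, exactly one
provider's connection variables, `RESULT_PATH`, `FS_PROVIDER_ID`,
`FS_PARADIGM`, and the manifest's declared variables -- nothing else. The
working directory is a throwaway copy of the package root; the `state/`
subtree is snapshotted (content-addressed) after each execution and
overlaid onto the next workspace, reproducing the stopped-container /
re-instantiated-container carry-over semantics at desk scale. Timeouts
(default 300 s per execution, 120 s in the scenario configs) surface as the
distinguished exit code 124; crashes are data, not exceptions.

### Engine and paradigms

* **IIL**: one round = one full pass over the provider order. Each hop is
  seeded with the previous hop's state; a failed hop terminates the pass
  and the remaining hops are reported `SKIP` (carrying a broken state
  forward would only produce cascading noise downstream of the real
  fault).
* **FL**: one replica per provider per round, launched in parallel, each
  seeded only with the previous round's global result (replicas are fresh
  each round; retaining per-provider local state would contradict the
  replica semantics, and a manifest flag is the place to revisit this).
  Replica results are collected under `AGGREGATION_INPUT_DIR/<provider>/`
  and the aggregator runs as its own execution; its artifact becomes the
  round's global result (S6). If any replica failed, aggregation is not
  attempted and S6 fails -- partial aggregation (`aggregate_partial`) is
  off by default because a smoke test should surface failures, not mask
  them.
* **FL-INC**: identical to FL but with the replica pool limited to one
  concurrent execution; the trace records execution intervals, so the
  observed maximum concurrency is measurable.

Step statuses per execution: S1 from connect/auth telemetry, S2 from query
telemetry, S3 from state evidence, S4 from the exit code, S5 from
result-artifact collection; the first failing step marks the later steps
of that execution `SKIP`, so exactly one requirement carries each fault.

On Requirement C's observability: whether prior results were semantically
*loaded into* the analysis cannot be verified without instrumenting user
code. C is therefore evaluated structurally -- a non-initial execution must
start with a non-empty prior result artifact in place, and the initial
execution counts as successful initialization if its workspace was
prepared. Whether the initial execution *produced* a result is already
Requirement E's question at that execution; counting it under C as well
would report one defect twice.

## Scenarios and fault injection

Three generated scenario bundles replicate the study settings with
synthetic stand-ins:

* `make_user_study_scenario()` -- two hospitals, both relational, with
  deliberately heterogeneous schemas: the patient relation is `patients`
  at Hospital A and `patient_info` at Hospital B, with differing extra
  columns (treatment history vs insurance). The reference analysis counts
  patients aged >= 50 across both sites; default 50 synthetic patients
  per hospital, ages uniform on [0, 100].
* `make_imaging_scenario()` -- three providers, each a FHIR-like server
  (Patient, Media, ImagingStudy) interlinked with an object store of
  64x64 synthetic JPEGs; 10 instances per entity. The reference analysis
  fetches every Media resource and reads every referenced blob.
* `make_tabular_scenario()` -- six providers with numeric feature tables
  (90 rows each, totalling ~540 records); running-statistics accumulator
  under IIL, pooled mean under FL.

The reference analyses replace model training with deterministic
accumulators on purpose: the criteria are agnostic to what S4 computes, so
a counting analysis exercises the same workflow as a classifier while
keeping every expected value computable by a brute-force oracle over the
generated records.

`inject_fault()` plants exactly one defect per bundle copy: `WRONG_PORT`
and `BAD_CREDENTIALS` corrupt one provider's injected connection
variables (targeting A), `SCHEMA_MISMATCH` switches the analysis to the
naive single-table query that breaks at Hospital B (targeting B), `CRASH`
raises after the query stage (D), `MISSING_RESULT` suppresses the artifact
write (E), and `AGGREGATOR_CRASH` fails the aggregation step (F; rejected
under IIL, which has no aggregation). The core property -- checked in the
tests and recomputed by `scripts/acceptance.R` -- is that this fault matrix
is diagonal: each fault fails its targeted requirement and only
requirements at or after the faulted step are non-PASS.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `n_per_entity` | 10 (50 in the user-study bundle) | study-scale instance counts; enough for non-trivial predicates, small enough for seconds-long tests |
| `rounds` | 1 | one full pass exercises every step; multi-round behavior is covered separately |
| `timeout` | 300 s (`execute_step`), 120 s (scenarios) | smoke tests must terminate; hangs become diagnosable S4 failures |
| `aggregate_partial` | `FALSE` | failed replicas must surface as S6 failures, not be averaged away |
| `strict` | `TRUE` | `UNOBSERVED` criteria withhold an overall PASS; a smoke test should not vouch for what it could not see |
| image size | 64x64 | smallest size that still exercises a real JPEG codec path |
| null probability | 0 | missingness is opt-in per attribute |

Ports are drawn from a seeded sequence in 20000-39999 with
availability-checked retry; credentials are seeded per provider. All
randomness flows through explicit stream objects derived from one root
seed, so identical (schema, config, seed) reproduce byte-identical
datasets, identical traces (up to timestamps) and identical reports.

## Problem sizes used by tests and the acceptance script

The test suite runs the full fault matrix at 20 patients per hospital, the
paradigm-equivalence check at 50 per hospital (the user-study scale), the
imaging scenario at 3 providers x 10 instances, and unit-level properties
on 5-200 records. These sizes were chosen as the package's own desk-scale
defaults: large enough that predicates and references are non-trivially
populated, small enough that the whole suite runs in well under a minute
of simulated executions.

## Known limitations

* The vocabulary is a faithful-by-structure reconstruction, not a
  wire-compatible copy of any platform's internal ontology; documents are
  portable within fedsmoke only.
* The embedded backends speak the gateway's JSON-line protocol, not the
  wire protocols of PostgreSQL/MongoDB/MinIO; analysis code written
  directly against those drivers needs the bundled client shim (or a
  container-based Database Plugin, which the plugin contract leaves open
  as an extension point).
* Requirement C is verified structurally (artifact presence), not
  semantically (values actually used) -- see above.
* FHIR resources carry minimal structure (type, id, subject/content
  references); no claim of FHIR conformance beyond that.
* Cross-provider network isolation is enforced at the credential level
  (each execution sees exactly one provider's variables), not as separate
  network namespaces.
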