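---
title: "Building analysis-ready data collection sets from heterogeneous EHR summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building analysis-ready data collection sets from heterogeneous EHR summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdelink)
```

## The problem

A pharmacoepidemiologist designing a post-marketing safety study thinks in
research vocabulary — SDTM domains and variables, MedDRA preferred terms —
while the electronic health records the study must run on are exposed in
whatever content model the source system speaks: an XML document dialect in
one region, an RDF graph in another, each with its own coding systems.
Classical integrations translate whole messages between models; every new
source then needs a new translator, and the researcher's analysis code is
welded to one target model.

`cdelink` takes the common-data-element route instead. Each *data element*
(a concept plus a value domain, in the ISO/IEC 11179 sense) is an abstract,
machine-processable definition held in a metadata registry. Elements of
different registries — research-side SDTM variables, the EHR-side common
information model, a document-bound data dictionary — are connected by
`skos:exactMatch` links, and the EHR-side elements carry *extraction
specifications*: executable scripts (XPath for document models, a SPARQL
basic-graph-pattern subset for graph models) that pull that element's value
out of a concrete patient summary. To evaluate a research variable against
a source, the engine walks the link chain from the variable to the first
element holding a specification for the source's content model, executes
it, and coerces the result to the variable's value domain. The researcher
never learns — and never needs to learn — which model served the request.

## The registry and link traversal

A registry dump (JSON) holds peer registries merged into one federated
store. Loading validates: globally unique element ids, no dangling link
targets, coded value domains naming their code system, at most one
specification per (element, content model).

`exactMatch` is stored directionally but traversed symmetrically, because
the relation is symmetric by definition. Resolution
(`resolve_extraction_spec()`) is a breadth-first search, so the returned
chain is *minimal* among all chains reaching a specification-bearing
element; among equally short chains the lexicographically smallest element
id wins. That tie-break is arbitrary but deterministic — the alternative
(first-loaded wins) would make results depend on file order. Nothing in
the registry model prefers one peer registry over another at equal depth;
if two truly different specifications ever sit at the same distance, the
schema author should bind the intended element directly.

`transitive_matches()` returns the whole exactMatch-connected component,
which is what a curator browsing mappings wants to see. Both operations
are property-tested against brute-force enumeration (all simple paths, and
a matrix-closure reachability oracle) on randomly generated registries of
up to 20 elements.

## Extraction and the entry anchor

Both dialects return values grouped by *clinical entry*. This is the one
structural commitment the engine makes about content models, and it is
forced by the schema language: an item like "date of first myocardial
infarction" pairs a problem *code* with the start *date* of the same
medical-history entry. Without a join key, code and date lists of a
patient with several conditions could be cross-combined, and windowed
means or first/last lookups would be ill-defined. So path results carry
the id of their nearest ancestor `entry` node (or `"document"` for
patient-level facts), graph results project an `?entry` variable, and
`extract_entries()` outer-joins element values on the entry id — entries
missing one element get an explicit null, values of different entries are
never mixed.

The graph dialect is deliberately small: `SELECT` over one basic graph
pattern plus `FILTER` equality, projecting `?entry` and `?value` and
optionally `?system` (so a coded value travels with its code system; the
XML side gets the same information from the `codeSystem` attribute next to
the matched `code` attribute). The restriction keeps a naive
all-assignments join oracle feasible, and every schema item the study
needs is expressible in it. Full SPARQL (OPTIONAL, UNION, property paths)
and full CDA validation are out of scope. Statements inside the pattern
use prefixed names only, since patterns are split on `.`.

Zero matches are never an error: real warehouses legitimately produce
empty columns (entire observation streams can be absent), and the engine
propagates explicit nulls end to end.

## Schemas and derivations

A data-collection-set schema is an ordered list of named items. Each item
binds one or more data elements (optionally fixing a code value, e.g. a
MedDRA preferred term, matched against warehouse codes through the
terminology service) and one derivation:

| function | meaning | null when |
|---|---|---|
| `VALUE` | the single extracted value (conflicting duplicates are a data-quality error) | no value |
| `FIRST_DATE` | earliest matching entry date (optionally on/after an index) | no matching entry |
| `EXISTS_BEFORE` / `EXISTS_AFTER` | "Y"/"N": any matching entry strictly before / on-or-after the index | index null |
| `MEAN_IN_WINDOW` | mean of values dated in `(index − window, index]` | no in-window value |
| `LAST_VALUE_BEFORE` | value with maximal date ≤ index | none before |
| `DATE_OFFSET` | index (or constant) + offset days | index null |
| `MIN_DATE` | minimum of present item references and constants | all absent |

Conventions, chosen once and fixed:

* **Windows are half-open**, `(index − w, index]`, at day granularity, so
  adjacent windows never double-count a boundary measurement. "Twelve
  months" is fixed at 365 days — calendar-month arithmetic would make
  results depend on the index date's month lengths.
* **"Before the start of ACS" is strictly before the event date;
  "after" is on-or-after the stabilized start** (event + 30 days),
  mirroring the protocol's 30-day stabilization delay. The shipped
  configs encode this as an `index_offset_days: 30` on the after-flag.
* **Ties in `LAST_VALUE_BEFORE`** (two measurements on the maximal date)
  resolve to the later entry in document order.

Items may reference other items (an index date, candidates of a
`MIN_DATE`), so `validate_schema()` derives the dependency graph, rejects
cycles naming the offenders, and emits a topological evaluation plan that
is stable: ties break by declaration order, and — a tested invariant —
*any* valid order yields the identical table.

## Cohort selection and incidence

The reference protocol: first ACS event (acute myocardial infarction or
unstable angina) during 2005–2011; at least one year of recorded history
before the event; alive 30 days after it; aged ≥ 18 at the event.
Exclusions are attributed to the *first* failing filter in that order,
making the exclusion table deterministic and auditable. Follow-up runs
from STARTDATE (event + 30 days) to LASTDATE (earliest of death,
transfer-out, 2011-12-31).

Two readings of "a *first* ACS event during 2005–2011" are defensible when
a patient has an earlier event before 2005; the package disqualifies such
patients by default (the in-window event is a recurrence, not a first
event) and exposes `pre_window_disqualifies = FALSE` for the other
reading.

`incidence_rate()` reports events per 1000 person-years: person-time per
member runs from STARTDATE to the event or LASTDATE, whichever is first
(365-day years); events count when dated in `(STARTDATE, LASTDATE]`. A
member accrued in the last 30 days of the window has LASTDATE before
STARTDATE and hence no observable follow-up; the default treats that as a
data-quality signal, while `zero_follow_up = "drop"` (used by the study
pipeline) removes such members, who can contribute neither events nor
person-time. Age is completed years at the event date. The standard error
reported is the usual Poisson normal approximation, `rate / sqrt(events)`.

## The synthetic population

The real deployment target — a regional warehouse of millions of patients
— is not available at desk scale, so the package ships a seeded generator
whose output has *known ground truth*: for every patient it records the
true first-ACS date, the eligibility verdict with its failing filter, CHF
flags and first post-ACS CHF date, the one-year pre-ACS systolic BP mean
and the last pre-ACS weight, all recomputable from the emitted records
(the tests do exactly that with an independent document scan).

The defaults define the package's reference study conditions and emulate
the *ACS-enriched* population an eligibility pre-query would return, not
the general population — hence a first-ACS exponential rate of 0.30/year
from mid-2004 (draws landing before 2005 exercise the first-event
disqualification; draws beyond the data horizon leave the patient without
an event). Female share 0.3822 and a later mortality of 0.07/year after a
10% 30-day case fatality reproduce the demographic texture reported for
the original deployment (≈38% female, ≈1/3 dying during follow-up). CHF
after the stabilized ACS arrives at 5 per 1000 person-years — inside the
2.3–11.9 band the UK Prospective Diabetes Study reported for diabetic
cohorts — and the parameter-recovery tests check the pipeline re-estimates
it. Observation streams (systolic/diastolic BP, HbA1c, weight) are noisy
Poisson-scheduled measurements with per-patient stream missingness; blood
pressure is missing for 60% of patients by default, deliberately mirroring
the mostly-empty BP columns real deployments observe. Transfers out are
drawn from after the ACS stabilization for ACS patients — a recorded
warehouse event cannot postdate the patient's exit from the system.

What the generator does *not* emulate: drug exposure, coding errors and
miscoding, duplicate records, calendar trends in incidence, correlation
between streams. Passing tests therefore demonstrate that the engine
recovers what the records contain — not that real warehouse data is this
clean.

A frozen reference population (n = 50, seed = 42) has its ground-truth
table checked into `inst/extdata/`; a test regenerates the population and
must reproduce it exactly, pinning the generator's behavior.

## Problem sizes and numerics

The test suite exercises: dual-rendering equivalence (graph vs XML,
cell-for-cell) on a 200-patient population; eligibility against a
brute-force oracle at n = 2000; single-seed CHF-rate recovery at n = 2000
(within three standard errors of the configured hazard) and a 20-seed
mean-rate recovery at n = 2000 per seed (within 5%); the female share at
n = 10000 (within three binomial standard errors). The large-n recovery
paths build the cohort table from canonical records via `study_table()`;
its agreement with the full semantic-extraction path over both renderings
is itself a tested invariant, so the recovery runs still certify the same
computation. Means are compared to ground truth at 1e-9 relative
tolerance; dates exactly.

## Worked example

```{r example, eval = FALSE}
library(cdelink)
pop <- generate(generator_config(n_patients = 200, seed = 8))
res <- run_study(pop$patients, schema_fixture("study"))
res$exclusions
res$overall      # events, person-years, rate per 1000 PY
head(res$dcs)
```

## Known limitations

* The terminology service is fixture-scale (about 20 concepts per system,
  one-hop concept maps); real MedDRA licensing, its hierarchy, and
  transitive cross-terminology chaining are out of scope — multi-hop
  chaining is deliberately not performed because it silently broadens
  clinical meaning.
* The two content models are simplified dialects that preserve the
  structural features the method depends on (section/entry nesting; typed
  triples), not full CCD or a production RDF information model.
* Registry federation is in-memory; no versioning, workflow states, or
  remote registries.
* Incidence reporting offers normal-approximation standard errors only;
  survival modelling is out of scope.
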