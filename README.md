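# cdelink

Common-data-element driven extraction of analysis-ready data collection
sets from heterogeneous EHR patient summaries, with cohort selection and
incidence-rate reporting for post-marketing drug-safety studies.

## Who this is for

Pharmacoepidemiologists and clinical-research informaticians who design
surveillance studies in research vocabulary (SDTM variables, MedDRA
preferred terms) but must execute them against electronic health records
exposed in arbitrary content models — an XML patient-summary document in
one source, an RDF graph in another, each coded in its own terminology
(ICD-9-CM on the warehouse side).

## The idea

Every study variable is an abstract **data element** in the ISO/IEC 11179
sense — a concept plus a value domain — held in a semantic metadata
registry. Elements of different registries are connected by
`skos:exactMatch` links, and EHR-side elements carry **extraction
specifications**: XPath scripts for document models, SPARQL
basic-graph-pattern scripts for graph models. To evaluate a variable
`e` against a summary in content model `m`, the engine finds the
shortest exactMatch chain

```
e = e_0 — e_1 — … — e_k,   e_k carries a spec for m,
```

executes that spec, and coerces the result to `e`'s value domain. A
schema item is then a derivation over the extracted, entry-joined values:

```
MEAN_IN_WINDOW(x; t0, w)  = mean{ x_i : t_i ∈ (t0 − w, t0] }
LAST_VALUE_BEFORE(x; t0)  = x_argmax{ t_i ≤ t0 }
EXISTS_BEFORE(c; t0)      = 1{ ∃ i : code_i ≈ c, t_i < t0 }
```

with code matching `≈` bridged through a MedDRA↔ICD-9-CM concept map.
Cohort reporting uses person-time at risk: for member `j` with follow-up
`(START_j, LAST_j]` and event time `T_j`,

```
rate = 1000 · Σ_j 1{T_j ∈ (START_j, LAST_j]} / Σ_j (min(T_j, LAST_j) − START_j)/365
```

events per 1000 person-years. The reference protocol: first acute
coronary syndrome (ACS) event during 2005–2011, ≥ 1 year of history,
alive 30 days after the event, aged ≥ 18; follow-up from event + 30 days
to the earliest of death, transfer-out, or 2011-12-31; outcome is
congestive heart failure (CHF) after the stabilized start.

A seeded synthetic-population generator with recorded ground truth stands
in for the (inaccessible) regional warehouse and defines the package's
reference study conditions; see the methods vignette
(`vignettes/data-collection-sets.Rmd`) for the model, conventions and
generator design.

## Worked example

```r
library(cdelink)
pop <- generate(generator_config(n_patients = 200, seed = 8))
res <- run_study(pop$patients, schema_fixture("study"))
```

The pipeline logs its eight data-flow steps to standard error and prints:

```
res$exclusions
#> no_first_acs_in_window   insufficient_history   death_within_30_days
#>                     40                      5                     12
#>          under_min_age
#>                      2

res$overall
#>   events person_years rate_per_1000py  se_rate
#> 1      2     520.6986        3.840993 2.715992

head(res$dcs[, c("patient_id","SEX","ACS_DATE","STARTDATE",
                 "CHF_BEFORE_ACS","SBP_MEAN_1Y_BEFORE_ACS")], 4)
#>   patient_id SEX   ACS_DATE  STARTDATE CHF_BEFORE_ACS SBP_MEAN_1Y_BEFORE_ACS
#> 1     P00001   M 2005-07-06 2005-08-05              N                     NA
#> 2     P00002   M 2006-12-28 2007-01-27              N                     NA
#> 3     P00004   M 2008-06-03 2008-07-03              N                     NA
#> 4     P00005   M 2006-04-19 2006-05-19              N                 142.05
```

Of 200 simulated patients, 141 form the ACS cohort (59 excluded, each
attributed to the first failing protocol filter); two CHF events over
~521 person-years give 3.8 per 1000 person-years — a small-sample
estimate of the generator's configured 5/1000 PY hazard. The mostly-`NA`
blood-pressure column is deliberate: the generator emulates sparsely
structured sources. The same run with `content_model_id = "CCD-XML"`
returns the identical table cell for cell — the researcher cannot tell
which content model served the extraction.

Element browsing shows the semantic machinery:

```r
describe_element("SDTM:MH.MHPTCD")
#> SDTM:MH.MHPTCD  (Medical History Preferred Term Code)
#>   value domain: code, code system MedDRA
#>   exactMatch closure: HITSP:7.04, SALUS:Condition.ProblemCode.CD
#>   CIM-RDF: graph_pattern spec held by SALUS:Condition.ProblemCode.CD via chain
#>            SDTM:MH.MHPTCD -> SALUS:Condition.ProblemCode.CD
#>   CCD-XML: path spec held by HITSP:7.04 via chain
#>            SDTM:MH.MHPTCD -> SALUS:Condition.ProblemCode.CD -> HITSP:7.04
#>   calculation options: VALUE, EXISTS_BEFORE, EXISTS_AFTER
```

A command-line wrapper over the same functions lives at
`inst/cli/cdelink.R` (`generate`, `run-study`, `describe-element`).

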