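# edcforge

A headless, metadata-driven **electronic data capture (EDC) engine** for
clinical studies, written in R.

Clinical research needs structured, validated data entry through electronic
case report forms (eCRFs), an auditable record of every change, and clean
exports — but commercial EDC systems are costly to license and deploy, and
small projects often fall back to error-prone spreadsheets. `edcforge`
provides the data-capture core such projects need, with no server or UI
required: everything is driven by *study metadata* (visits, input widgets,
controlled vocabularies, skip-logic conditions), and every stored value is
an immutable row in an append-only audit store.

It is aimed at clinical researchers and data managers who want a scriptable,
reproducible capture backend — for retrospective chart abstraction on a
laptop, multi-device offline collection with later merging, or as the engine
beneath a study-specific front end.

## What the engine does

* **Metadata-driven eCRFs** — nine input types (text, integer, float,
  checkbox, time, date, radio, dropdown, searchable dropdown over
  vocabularies such as ICD-10), per-visit or participant-centered
  assignment, requiredness, units, and display conditions with a canonical
  skip-logic grammar: `ALL(age ge 18, ANY(sex eq "f", dx in_set {"J45.9"}))`.
* **Validated entry** — submissions are flat key→string records; values are
  coerced to canonical typed forms, required-field checks apply only to
  visible widgets and only on complete submissions, and values for hidden
  widgets are stripped with a warning.
* **Append-only audit store** — rows are never updated or deleted; edits
  append versions, deletions append tombstones carrying the deleted payload.
  `query_as_of(store, t)` reconstructs the exact database state at any past
  time point; `store_digest()` gives tamper evidence over any row prefix.
* **Two-phase lifecycle** — metadata is authored and previewed in *editor*
  mode; *deployment* activation requires clean validation, purges preview
  data, and freezes existing visits. Clinical data is recorded permanently
  only in deployment mode. Reversal is admin-only and accepts only additive
  metadata changes afterwards.
* **Pseudonymized inclusion** — participants get IDs `{site}-{seq:04d}`;
  `pid_exists()` is the whole contract a mobile client needs;
  `documentation_status()` reports empty/partial/complete per visit
  instance.
* **Reproducible exports** — a zip bundle with per-visit tables, an
  aggregated wide table (also CSV/XLSX), the full metadata, an
  auto-generated codebook, the audit log and a row-count manifest —
  byte-identical across runs given an injected timestamp.
* **Offline merge** — audit stores from independently operated devices merge
  as a union keyed by `(record_id, version_no, origin_id)`; the strict
  policy is idempotent, commutative and associative, and conflicts (possible
  only for diverged copies of a seeded database) are detected and reported.
* **FHIR import** — R4 Questionnaires map to variable sets (including
  `enableWhen` → skip logic); QuestionnaireResponses become ordinary
  validated submissions.
* **Synthetic studies** — a deterministic generator produces studies and
  full capture campaigns at multi-center scale (reference workload:
  679 variables per participant, 1,700 participants across 4 sites) for
  testing and demonstration.

## Worked example

```r
library(edcforge)

study <- study_metadata(
  "pilot_gi", "GI bleeding pilot",
  visits = list(
    visit_definition("baseline", "Baseline", 0L),
    visit_definition("intervention", "Intervention", 1L, repeating = TRUE)),
  widgets = list(
    widget_definition("age", "integer", "Age", required = TRUE,
                      visit_ids = "baseline", units = "years", order_index = 0L),
    widget_definition("sex", "radio", "Sex", required = TRUE,
                      visit_ids = "baseline",
                      choices = list(c("f", "Female"), c("m", "Male")),
                      order_index = 1L),
    widget_definition("pregnant", "checkbox", "Currently pregnant",
                      visit_ids = "baseline", condition = 'sex eq "f"',
                      order_index = 2L),
    widget_definition("dx", "dropdown_search", "Admission diagnosis",
                      visit_ids = "baseline", lookup_table_id = "icd10_demo",
                      order_index = 3L),
    widget_definition("tx_time", "time", "Time of intervention",
                      visit_ids = "intervention", order_index = 4L)),
  lookup_tables = list(demo_lookup_table()))

validate_study_metadata(study)
#> <validation report: ok>

state <- study_state(study, clock = fixed_clock())  # injectable clock
activate_deployment(state, "study_nurse")
p <- include_participant(state, "muc", "study_nurse")
p$pid
#> [1] "muc-0001"

submit_entry(state, p$pid, "baseline",
             c(age = "63", sex = "f", pregnant = "false", dx = "K92.2"),
             actor = "study_nurse")
submit_entry(state, p$pid, "intervention", c(tx_time = "14:35"),
             actor = "study_nurse")
documentation_status(state, p$pid)
#>       visit_id visit_instance   status
#> 1     baseline              1 complete
#> 2 intervention              1 complete
```

An amendment appends a new version; the audit chain keeps both:

```r
submit_entry(state, p$pid, "baseline", c(age = "64"), actor = "study_monitor")
#> v1 2024-01-01T08:00:03.000Z study_nurse   age=63
#> v2 2024-01-01T08:00:05.000Z study_monitor age=64   (history() of the record)

export_aggregated(state$store, study)
#>        pid baseline.age baseline.sex baseline.pregnant baseline.dx intervention.1.tx_time
#> 1 muc-0001           64            f             false       K92.2                  14:35

write_bundle(state$store, study, "pilot_bundle.zip",
             timestamp = "2024-09-01T00:00:00.000Z")$members
#>  [1] "audit/audit_log.csv"    "codebook.csv"           "data/aggregated_wide.csv"
#>  [4] "data/baseline.csv"      "data/intervention.csv"  "data/participants.csv"
#>  [7] "manifest.json"          "metadata/choices.csv"   "metadata/conditions.csv"
#> [10] "metadata/lookup_tables/icd10_demo.csv"           "metadata/manifest.json"
#> [12] "metadata/visits.csv"    "metadata/widgets.csv"
```

The numbers mean: one participant (`muc-0001`) with a complete baseline and
one intervention instance; after the amendment the aggregated export shows
the current head value (`age = 64`) while both versions remain in
`audit/audit_log.csv`; and the bundle contains data, metadata, codebook and
audit trail as separate plain-text members.

## Documentation

The methods vignette (`vignettes/edcforge-methods.Rmd`) describes the data
model, the condition grammar and its semantics, the audit-store ordering
and clock-skew rules, lifecycle and merge design choices, the FHIR mapping,
what the synthetic-data generator does and does not emulate, and known
limitations.
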