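---
title: "edcforge: design and methods of a metadata-driven EDC engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{edcforge: design and methods of a metadata-driven EDC engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcforge)
```

## The problem

Clinical studies need structured, validated data capture: an electronic case
report form (eCRF) per participant and visit, completeness checks at entry
time, an auditable record of every change, and an export that a statistician
can load without reverse-engineering the database. Commercial electronic data
capture (EDC) systems provide this at substantial cost and setup effort;
small research projects often fall back to spreadsheets, with the data
quality problems that entails.

`edcforge` is a headless EDC engine for exactly this niche. Everything a
study-specific user interface would do — render forms, validate input,
record versions, export datasets — is driven by *study metadata*: a machine-
readable description of visits, input widgets, controlled vocabularies and
display conditions. The package contains no UI; its contract is functions, a
JSON project file, and a thin command-line interface.

## The metadata model

A study is described by `study_metadata()`: visits (`visit_definition()`),
widgets (`widget_definition()`) and lookup tables (`lookup_table()`).

Each widget carries one variable's complete definition: one of nine input
types (`text`, `integer`, `float`, `checkbox`, `time`, `date`, `radio`,
`dropdown`, `dropdown_search`), a label, a requiredness flag, the visits it
appears in, a choice list (for radio/dropdown), a lookup-table reference
(for searchable dropdowns over vocabularies such as ICD-10 or ICHI), an
ordering index, and optionally units, help text and a display condition.
A widget with no visit assignment is *participant-centered*: its data
(diagnoses, medications) is captured independently of visits under the
reserved pseudo-visit id `"participant"`.

Two identifier charsets are used deliberately. Variable, visit, study and
lookup-table identifiers are lowercase snake case (at most 64 characters) so
that every identifier is safe as a CSV column name across export formats.
Vocabulary *codes* (choice codes, lookup codes) use a wider charset
(`[A-Za-z0-9][A-Za-z0-9_.-]*`) because real dictionaries use entries such as
`J45.9`; restricting codes to snake case would make genuine ICD-10 uploads
impossible.

Validation never throws: `validate_widget_definition()` and
`validate_study_metadata()` return reports whose entries carry machine-
readable codes (`DUPLICATE_ID`, `MISSING_CHOICES`, `BAD_LOOKUP_REF`,
`CONDITION_UNKNOWN_VAR`, `CONDITION_TYPE_MISMATCH`, `CONDITION_CYCLE`, ...).
An empty report is a hard precondition for deployment activation.

## Display conditions

The engine needs a skip-logic grammar; we use a deliberately minimal tree of
`ALL(...)`/`ANY(...)` combinators over atoms `variable OP literal`, with
operators `eq ne lt le gt ge in_set is_empty not_empty` and a canonical
string form (`parse_condition()` / `serialize_condition()` are exact
inverses):

```{r}
cond <- cnd_all(cnd_atom("age", "ge", 18),
                cnd_any(cnd_atom("sex", "eq", "f"),
                        cnd_atom("dx", "in_set", c("J45.9", "I10"))))
serialize_condition(cond)
```

Semantics are fixed by three rules that make evaluation total:

* an atom referencing an unanswered variable is `FALSE`, except `is_empty`,
  which is `TRUE`;
* `ALL()` of no children is `TRUE`, `ANY()` of no children is `FALSE`;
* ordered comparisons (`lt le gt ge`) are defined only for `integer`,
  `float`, `date` and `time` widgets. Dates and times compare as their
  canonical ISO strings, whose fixed width makes lexicographic order equal
  chronological order.

Type checking of a condition against the referenced widget happens at
metadata validation time (numeric literals for numeric widgets, boolean for
checkboxes, choice-code membership for radio/dropdown), and the condition
dependency graph must be acyclic, checked by depth-first search.

## Input coercion

Raw submissions are flat maps from variable id to string — what any form
front end or CSV row provides. `coerce_value()` defines the accepted
canonical forms; `render_value()` is its inverse and produces the strings
that are stored and exported:

* integers: base-10 with optional sign, no grouping separators;
* floats: `.` as the decimal separator, up to 15 significant digits on
  rendering (locale normalization such as `","` input is a front-end
  concern, not the engine's);
* checkboxes: `true/false/1/0` case-insensitively in, `true`/`false` out;
* dates: `YYYY-MM-DD`, validated as real calendar dates (`2021-02-30` is
  rejected, not silently shifted);
* times: 24-hour `HH:MM` — minute precision is deliberate; clinical visit
  documentation does not record seconds;
* radio/dropdown: one of the widget's choice codes; searchable dropdowns:
  one of the lookup table's codes.

The empty string is the explicit missing value for every type. Coercion
failures are values, not exceptions; they surface as `COERCION_ERROR`
entries in validation reports.

`validate_submission()` distinguishes completeness semantics: with the
submission's `complete` flag set, every *visible* required widget must be
filled (`MISSING_REQUIRED`); without it (a partial save), only type checks
apply — the engine never stores uncoercible data, but tolerates incomplete
forms. Values supplied to widgets hidden by skip logic are reported as
warnings (`VALUE_FOR_HIDDEN`) and stripped before storage, so contradictory
skip-logic data cannot enter the database. Visibility during validation is
re-evaluated against the *effective* values (submitted where given, stored
otherwise), so a submission that toggles a controlling answer is judged
against the state it creates.

## The append-only audit store

All persistence goes through one primitive: the audit row. A logical record
(a participant registration, or the value set of one participant-visit
instance) is a chain of immutable versions; edits append version `n+1`,
deletions append a row with `deleted = TRUE` carrying an unchanged copy of
the deleted payload, so every row is self-describing. Rows are never
updated or removed, which yields two properties the package tests
aggressively:

* **tamper evidence** — the SHA-256 digest over any prefix of rows
  (`store_digest()`) is invariant under all later operations;
* **time travel** — `query_as_of()` reconstructs the exact database state
  at any past instant, because the present never rewrites the past.

Ordering authority is `(timestamp, row_seq)`. Timestamps are fixed-width
UTC ISO 8601 strings with milliseconds, injected through a clock function
(`system_clock()` in production, `fixed_clock()` for reproducible runs).
When an appended row's clock reads earlier than its record's head — offline
devices with skewed clocks — the timestamp is clamped to head + 1 ms and a
`CLOCK_SKEW` event is logged. Clamping keeps every chain strictly monotone
without rejecting field data, which we judged safer than erroring during
data collection.

The store itself is an in-memory append-only table with plain-text
persistence: the JSON project file (`save_study()`/`load_study()`) and the
`audit_log.csv` export (payloads JSON-encoded in one column). The row
contract is engine-agnostic; a SQL backend could be substituted without
changing any caller.

Record identities are version-4 UUIDs drawn from R's seeded random stream:
reproducible in simulations, and collision-free across independently
operated devices, which is what makes offline merging tractable.

## Study lifecycle

A study begins in **editor** mode: metadata is authored (`add_visit()`,
`add_widget()`, `import_variable_set()`, FHIR import) and forms can be
previewed; preview entries land in a transient store. `activate_deployment()`
requires a clean validation report, purges the preview store (test entries
are never carried over), freezes the current visit definitions and opens
permanent capture. Only in deployment mode is clinical data recorded
permanently — a property the test suite asserts over randomized editor-mode
operation sequences.

`revert_to_editor()` is administrator-only and leaves all captured data
untouched. After a reversal, only *additive* changes are accepted: new
visits, new widgets, widened choice lists, relaxed requiredness. Narrowing
changes to deployed metadata (removing widgets or choices, changing a type,
making an optional field required) are rejected with `NARROWING_CHANGE`,
and deployed visits stay frozen (`VISIT_FROZEN`) across any number of
editor excursions. This operationalizes schema-integrity protection while
still supporting protocol amendments — the usual pain point that forces
database resets in other systems.

Participants are included with `include_participant()`, which assigns
pseudonymized IDs `{site}-{seq:04d}` — sequential per site for human
readability and mergeability; the scheme carries no identifying
information by construction. `pid_exists()` is the entire server-side
contract a mobile client needs before serving a form.
`documentation_status()` reports `empty`/`partial`/`complete` per visit
instance, where `complete` means the last stored submission asserted
completeness (and therefore validated cleanly when persisted).

## Export

`write_bundle()` produces the complete downloadable artifact: per-visit
tables, the participant registry, an aggregated wide table (one row per
participant; columns `visit.variable`, `visit.k.variable` for the k-th
instance of a repeating visit, `participant.variable` for
participant-centered data), the full metadata bundle, an auto-generated
codebook (one row per widget with serialized choices and conditions), the
complete audit log, and a manifest listing every member with its data-row
count. Deleted records appear only in the audit log.

Byte reproducibility is a design goal: given the same store and an injected
timestamp, two exports are identical bit-for-bit. That dictated several
numerical/format choices: CSVs are RFC 4180, UTF-8, LF, quoted only when
necessary; zip members are stored uncompressed in sorted order with the
injected timestamp as the only date; the XLSX writer emits a minimal
single-sheet workbook with inline strings (CSV remains the canonical,
information-preserving format — R-specific serialized exports were dropped
in favor of portable ones).

## Offline merge

Several devices can run the same deployment offline; afterwards their
stores are merged. Rows are keyed `(record_id, version_no, origin_id)`;
because record ids are device-generated UUIDs, independent devices are
conflict-free by construction and the merge is a pure union. Byte-identical
duplicates (re-merges, shared seed data) are deduplicated. The same key
with differing payload digests — possible only when copies of a seeded
database diverge — is a conflict: the default `strict` policy aborts with a
report, `latest_wins` keeps the later `(timestamp, row_seq)` row and logs
the loser.

Merged `row_seq` values are reassigned in
`(timestamp, record_id, version_no, origin_id)` order. Using a fully
content-determined tie-break (rather than source position) is what makes
the strict merge commutative and associative, which the tests assert
directly; ties across devices at the same millisecond are otherwise
arbitrary.

PID collisions can occur when devices share a site prefix. Colliding
origins are remapped deterministically: origins are ranked
lexicographically and each colliding origin after the first has its
per-site sequence offset by `rank × stride`, with the stride the next power
of ten above the largest sequence seen (at least 10 000). Remaps are
applied to the origin's participant and visit rows and listed in the merge
report.

## FHIR import

The bridge reads FHIR R4 JSON from files or byte streams (server transport
is deliberately out of scope; the testable contract is the mapping).
Questionnaire items map to widgets: `string/text→text`, `integer→integer`,
`decimal→float`, `boolean→checkbox`, `date→date`, `time→time`; `choice`
becomes a radio when it has at most 7 answer options and a dropdown
otherwise (a UI convention — the threshold is recorded as a warning in the
import report so importers can override it); `open-choice` becomes a
searchable dropdown over a lookup table built from its options. Groups are
flattened with dotted id prefixes, then linkIds are sanitized
deterministically into the identifier charset. `enableWhen` clauses become
condition atoms combined with `ALL` (or `ANY` under `enableBehavior =
"any"`); `exists` maps to `not_empty`/`is_empty`. Unsupported item types
(attachment, reference, quantity, display) are skipped with reasons.

QuestionnaireResponses become ordinary submissions (`status == "completed"`
maps to the completeness flag) and flow through `validate_submission()` and
the audit store like any hand-entered form — the bridge never writes to
the store directly, so imported data obeys every validation rule.

## The synthetic-study generator

There is no bundled real study data; `generate_demo_metadata()` and
`simulate_entries()` generate studies and capture campaigns with the
structural properties of real multi-center use, at the scale of the largest
documented deployments of such systems: up to 679 variables per participant
across two visits, and 1,700 participants across four sites. Those two
numbers are the package's reference workload; the acceptance script and the
scale test run it in full.

The generator's aim is structural coverage, not clinical realism: every
input type occurs (first nine widgets, one per type), a configurable
fraction of widgets gets display conditions referencing earlier widgets of
the same form scope (acyclic and evaluable by construction), a small
fraction is participant-centered, repeating visits get second instances,
and campaigns inject partial saves, amendments and soft deletions to
exercise the audit chain. Value generators draw from fixed plausible ranges
(ages 0–120, measurements 0–500, dates within a study year); missingness is
injected only into non-required visible fields so that complete submissions
validate by construction. Everything is deterministic under the
configuration seed, including timestamps (a fixed clock) and record UUIDs
(seeded RNG).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: correlated or longitudinally coherent values,
realistic missingness mechanisms, free-text noise, mid-study metadata
amendments with live data, or concurrent multi-user entry.

## Problem sizes used by the test suite

Unit tests run on small hand-built studies (6 widgets) and generated ones
(9–120 widgets, up to 250 participants). Property tests use 400–1,000
random condition trees against a brute-force evaluator, 60–100 fuzzed
values per input type, 500-operation audit scenarios at 5 seeds with
snapshot replay and prefix digests, and 100+ metadata round trips. The
scale test and the acceptance script run the full reference workload
(679 × 1,700) end to end, including the complete bundle export.

## Known limitations

* Single-process, single-writer semantics; no concurrent editing or
  transactions beyond serialized in-process calls.
* No authentication or identity management — roles (`user`/`admin`) are
  caller-supplied tokens, as access control belongs to the deployment
  stack.
* No cross-field arithmetic validation (ranges, sum checks) beyond type and
  choice membership.
* The XLSX writer targets bulk export fidelity, not spreadsheet styling;
  all cells are strings.
* FHIR import covers Questionnaire/QuestionnaireResponse (R4); terminology
  server expansion of ValueSets is out of scope.
* One widget cannot have different requiredness in different visits;
  requiredness is a widget-level property.
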