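Package: edcforge
Title: Metadata-Driven Electronic Data Capture for Clinical Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless electronic data capture (EDC) engine for clinical
    research. Study metadata (visits, input widgets, controlled-vocabulary
    lookup tables, skip-logic conditions) drives form rendering, input
    validation and coercion for nine input types. Clinical entries are
    persisted in an append-only audit store from which the database state at
    any past time point can be reconstructed. Includes the editor/deployment
    study lifecycle with pseudonymized participant inclusion, export of the
    complete study dataset as a reproducible zip bundle with an automatically
    generated codebook, merging of audit stores from independently operated
    offline devices, import of study metadata from FHIR Questionnaire
    resources and of clinical data from FHIR QuestionnaireResponse resources,
    a synthetic-study generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
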