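test_that("a minimal valid radio widget passes validation", {
  study <- tiny_study()
  w <- widget_definition("consent", "radio", "Consent given",
                         visit_ids = "baseline",
                         choices = list(c("y", "Yes"), c("n", "No")))
  expect_true(report_ok(validate_widget_definition(w, study)))
})

test_that("the nine supported input types are accepted, others rejected", {
  study <- tiny_study()
  for (ty in INPUT_TYPES) {
    w <- widget_definition(
      "probe", ty, "Probe",
      choices = if (ty %in% c("radio", "dropdown"))
        list(c("a", "A"), c("b", "B")),
      lookup_table_id = if (ty == "dropdown_search") "icd10_demo")
    expect_true(report_ok(validate_widget_definition(w, study)), label = ty)
  }
  bad <- widget_definition("probe", "slider", "Probe")
  rep <- validate_widget_definition(bad, study)
  expect_true("UNKNOWN_INPUT_TYPE" %in% rep$code)
})

test_that("structural widget problems get machine-readable codes", {
  study <- tiny_study()
  rep <- validate_widget_definition(
    widget_definition("dx2", "dropdown_search", "Diagnosis",
                      lookup_table_id = "icd10"), study)
  expect_true("BAD_LOOKUP_REF" %in% rep$code)

  rep <- validate_widget_definition(
    widget_definition("one", "radio", "One choice",
                      choices = list(c("y", "Yes"))), study)
  expect_true("MISSING_CHOICES" %in% rep$code)

  rep <- validate_widget_definition(
    widget_definition("age", "integer", "Another age"), study)
  expect_true("DUPLICATE_ID" %in% rep$code)

  rep <- validate_widget_definition(
    widget_definition("bmi", "float", "BMI",
                      condition = "weight_kg gt 0"), study)
  expect_true("CONDITION_UNKNOWN_VAR" %in% rep$code)

  rep <- validate_widget_definition(
    widget_definition("bmi", "float", "BMI",
                      condition = cnd_atom("age", "eq", "old")), study)
  expect_true("CONDITION_TYPE_MISMATCH" %in% rep$code)
})

test_that("study-level validation finds duplicates and cycles", {
  study <- tiny_study()
  study$widgets <- c(study$widgets,
                     list(widget_definition("age", "integer", "Age again",
                                            visit_ids = "baseline",
                                            order_index = 9L)))
  expect_true("DUPLICATE_ID" %in% validate_study_metadata(study)$code)

  cyc <- study_metadata(
    "cyclic", visits = list(visit_definition("v1", order_index = 0L)),
    widgets = list(
      widget_definition("a", "integer", "A", visit_ids = "v1",
                        condition = "b ge 1", order_index = 0L),
      widget_definition("b", "integer", "B", visit_ids = "v1",
                        condition = "a ge 1", order_index = 1L)
    ))
  expect_true("CONDITION_CYCLE" %in% validate_study_metadata(cyc)$code)

  # igraph as the independent cycle oracle over generated condition graphs
  withr::with_seed(7, {
    for (rep_i in 1:25) {
      n <- 6
      ids <- sprintf("w%d", 1:n)
      edges <- integer(0)
      widgets <- lapply(1:n, function(i) {
        cond <- NULL
        if (i > 1 && runif(1) < 0.6) {
          j <- sample((1:n)[-i], 1)
          edges <<- c(edges, i, j)
          cond <- cnd_atom(ids[j], "ge", 1)
        }
        widget_definition(ids[i], "integer", ids[i], visit_ids = "v1",
                          condition = cond, order_index = i - 1L)
      })
      st <- study_metadata("graph_check",
                           visits = list(visit_definition("v1", order_index = 0L)),
                           widgets = widgets)
      g <- igraph::make_empty_graph(n, directed = TRUE)
      if (length(edges) > 0) g <- igraph::add_edges(g, edges)
      has_cycle <- !igraph::is_dag(g)
      expect_identical("CONDITION_CYCLE" %in% validate_study_metadata(st)$code,
                       has_cycle)
    }
  })
})

test_that("visit order indices must be unique", {
  study <- tiny_study()
  study$visits[[2]]$order_index <- 0L
  expect_true("DUPLICATE_VISIT_ORDER" %in% validate_study_metadata(study)$code)
})

test_that("variable-set import appends, suffixes collisions, stays valid", {
  study <- tiny_study()
  set <- variable_set("vitals", list(
    widget_definition("pulse", "integer", "Pulse", units = "bpm"),
    widget_definition("bp_sys", "integer", "Systolic BP", units = "mmHg"),
    widget_definition("age", "integer", "Age at visit")  # collides
  ))

  empty <- study_metadata("fresh",
                          visits = list(visit_definition("v1", order_index = 0L)))
  out <- import_variable_set(set, empty, "v1")
  expect_identical(widget_ids(out), c("pulse", "bp_sys", "age"))
  expect_identical(vapply(out$widgets, function(w) w$order_index, integer(1)),
                   0:2)
  expect_identical(out$metadata_version, 2L)

  out2 <- import_variable_set(set, study, "followup")
  expect_true("age_2" %in% widget_ids(out2))
  expect_true(report_ok(validate_study_metadata(out2)))

  # importing the same set twice keeps the study valid, all ids suffixed
  out3 <- import_variable_set(set, out2, "followup")
  expect_true(all(c("pulse_2", "bp_sys_2", "age_3") %in% widget_ids(out3)))
  expect_true(report_ok(validate_study_metadata(out3)))

  expect_edc_error(import_variable_set(set, study, "nope"), "UNKNOWN_VISIT")
})

test_that("set-internal condition references follow renamed ids", {
  set <- variable_set("pair", list(
    widget_definition("age", "integer", "Age"),
    widget_definition("adult_note", "text", "Note", condition = "age ge 18")
  ))
  study <- tiny_study()  # already defines "age"
  out <- import_variable_set(set, study, "followup")
  w <- out$widgets[[which(widget_ids(out) == "adult_note")]]
  expect_identical(serialize_condition(w$condition), "age_2 ge 18")
  expect_true(report_ok(validate_study_metadata(out)))
})

test_that("import into a study state requires editor mode", {
  state <- deployed_tiny_state()
  set <- variable_set("vitals", list(widget_definition("pulse", "integer", "Pulse")))
  expect_edc_error(import_variable_set(set, state, "baseline"),
                   "STUDY_NOT_IN_EDITOR_MODE")
})
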