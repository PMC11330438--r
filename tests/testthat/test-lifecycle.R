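test_that("deployment activation gates on validation and purges previews", {
  study <- tiny_study()
  state <- study_state(study, clock = fixed_clock())
  # preview entry in editor mode goes to the transient store
  submit_entry(state, "preview-1", "baseline",
               list(age = "50", sex = "m"), "tester")
  expect_identical(store_size(state$preview_store), 1L)
  expect_identical(store_size(state$store), 0L)

  activate_deployment(state, "admin")
  expect_identical(state$mode, "deployment")
  expect_identical(store_size(state$preview_store), 0L)  # purged
  expect_identical(store_size(state$store), 0L)
  expect_edc_error(activate_deployment(state, "admin"), "ALREADY_DEPLOYED")

  bad <- study_metadata(
    "bad_study", visits = list(visit_definition("v1", order_index = 0L)),
    widgets = list(widget_definition("x", "radio", "X", visit_ids = "v1")))
  bad_state <- study_state(bad)
  err <- expect_edc_error(activate_deployment(bad_state, "admin"),
                          "INVALID_METADATA")
  expect_true("MISSING_CHOICES" %in% err$data$report$code)
})

test_that("deployed visits are frozen through later editor excursions", {
  state <- deployed_tiny_state()
  expect_edc_error(
    edit_visit(state, visit_definition("baseline", "Renamed", 0L)),
    "STUDY_NOT_IN_EDITOR_MODE")

  expect_edc_error(revert_to_editor(state, "user1"), "NOT_ADMIN")
  before_rows <- store_size(state$store)
  revert_to_editor(state, "admin1", role = "admin")
  expect_identical(state$mode, "editor")
  expect_identical(store_size(state$store), before_rows)

  expect_edc_error(
    edit_visit(state, visit_definition("baseline", "Renamed", 0L)),
    "VISIT_FROZEN")
  expect_edc_error(remove_visit(state, "followup"), "VISIT_FROZEN")
  expect_edc_error(remove_widget(state, "age"), "NARROWING_CHANGE")

  # additive changes are fine; the new visit stays editable until deployed
  add_visit(state, visit_definition("extra", "Extra visit", 5L))
  edit_visit(state, visit_definition("extra", "Extra visit renamed", 5L))
  add_widget(state, widget_definition("new_var", "text", "New",
                                      visit_ids = "extra", order_index = 10L))
  frozen_before <- state$frozen_visits
  activate_deployment(state, "admin1")
  expect_true(all(frozen_before %in% state$frozen_visits))
  expect_true("extra" %in% state$frozen_visits)
  expect_edc_error({
    revert_to_editor(state, "admin1", role = "admin")
    edit_visit(state, visit_definition("extra", "Again", 5L))
  }, "VISIT_FROZEN")
})

test_that("narrowing changes to deployed widgets are rejected", {
  state <- deployed_tiny_state()
  revert_to_editor(state, "adm", role = "admin")
  # widening the choice list is allowed
  update_widget(state, widget_definition(
    "sex", "radio", "Sex", required = TRUE, visit_ids = "baseline",
    choices = list(c("f", "Female"), c("m", "Male"), c("x", "Other")),
    order_index = 1L))
  # dropping a choice is not
  expect_edc_error(update_widget(state, widget_definition(
    "sex", "radio", "Sex", required = TRUE, visit_ids = "baseline",
    choices = list(c("f", "Female"), c("x", "Other")), order_index = 1L)),
    "NARROWING_CHANGE")
  # changing the input type is not
  expect_edc_error(update_widget(state, widget_definition(
    "age", "float", "Age", required = TRUE, visit_ids = "baseline",
    order_index = 0L)), "NARROWING_CHANGE")
  # making an optional field required is not
  expect_edc_error(update_widget(state, widget_definition(
    "dx", "dropdown_search", "Main diagnosis", required = TRUE,
    visit_ids = "baseline", lookup_table_id = "icd10_demo",
    order_index = 3L)), "NARROWING_CHANGE")
})

test_that("participant inclusion follows the per-site PID scheme", {
  state <- deployed_tiny_state()
  p1 <- include_participant(state, "muc", "doc")
  expect_identical(p1$pid, "muc-0001")
  p2 <- include_participant(state, "muc", "doc")
  expect_identical(p2$pid, "muc-0002")
  b1 <- include_participant(state, "ber", "doc")
  expect_identical(b1$pid, "ber-0001")

  expect_true(pid_exists(state, "muc-0002"))
  expect_false(pid_exists(state, "muc-0099"))
  soft_delete(state$store, p2$record_id, "doc")
  expect_false(pid_exists(state, "muc-0002"))

  editor <- study_state(tiny_study())
  expect_edc_error(include_participant(editor, "muc", "doc"), "NOT_DEPLOYED")
})

test_that("many inclusions stay unique and sequential", {
  state <- deployed_tiny_state()
  pids <- vapply(1:250, function(i) {
    include_participant(state, c("muc", "ber")[1 + i %% 2], "doc")$pid
  }, character(1))
  expect_identical(length(unique(pids)), 250L)
  expect_identical(length(ls(state$participants)), 250L)
  expect_identical(sort(pids[grepl("^muc", pids)])[125], "muc-0125")
})

test_that("documentation status distinguishes empty, partial and complete", {
  state <- deployed_tiny_state()
  p <- include_participant(state, "muc", "doc")
  st0 <- documentation_status(state, p$pid)
  expect_identical(st0$status, c("empty", "empty", "empty"))

  submit_entry(state, p$pid, "baseline",
               list(age = "44", sex = "f", pregnant = "false", dx = "I10"),
               "doc", complete = TRUE)
  st1 <- documentation_status(state, p$pid)
  expect_identical(st1$status[st1$visit_id == "baseline"], "complete")
  expect_identical(st1$status[st1$visit_id == "followup"], "empty")

  submit_entry(state, p$pid, "followup", list(note = "recovering"), "doc",
               complete = FALSE)
  st2 <- documentation_status(state, p$pid)
  expect_identical(st2$status[st2$visit_id == "followup"], "partial")

  # repeating visit instances are listed individually
  submit_entry(state, p$pid, "followup", list(note = "second episode"), "doc",
               visit_instance = 2L, complete = TRUE)
  st3 <- documentation_status(state, p$pid)
  fu <- st3[st3$visit_id == "followup", ]
  expect_identical(fu$visit_instance, 1:2)
  expect_identical(fu$status, c("partial", "complete"))

  expect_edc_error(documentation_status(state, "muc-9999"),
                   "UNKNOWN_PARTICIPANT")
})

test_that("stored entries strip hidden values and respect skip logic", {
  state <- deployed_tiny_state()
  p <- include_participant(state, "muc", "doc")
  # sex=m hides 'pregnant'; a supplied value is stripped before storage
  submit_entry(state, p$pid, "baseline",
               list(age = "60", sex = "m", pregnant = "true", dx = "I10"),
               "doc", complete = TRUE)
  row <- edcforge:::current_entry_row(state, p$pid, "baseline", 1L)
  expect_false("pregnant" %in% names(row$payload$values))
  expect_identical(row$payload$values$age, "60")

  # an invalid complete submission is not persisted
  n <- store_size(state$store)
  expect_edc_error(
    submit_entry(state, p$pid, "baseline", list(age = ""), "doc",
                 complete = TRUE),
    "SUBMISSION_INVALID")
  expect_identical(store_size(state$store), n)
})

test_that("clinical data never reaches the permanent store before deployment", {
  withr::with_seed(505, {
    for (seed in 1:5) {
      cfg <- demo_config(seed = 500 + seed, n_widgets = 10, n_visits = 2)
      study <- generate_demo_metadata(cfg)
      state <- study_state(study, clock = fixed_clock())
      # a random editor-mode operation sequence with preview entries
      lut <- if (length(study$lookup_tables)) study$lookup_tables[[1]]
      for (i in 1:15) {
        visit <- sample(edcforge:::visit_ids_of(study), 1)
        vals <- edcforge:::demo_fill_form(study, visit, cfg, lut)
        submit_entry(state, sprintf("preview-%d", i), visit, vals, "tester",
                     complete = FALSE)
      }
      expect_identical(store_size(state$store), 0L)
      expect_true(length(query_current(state$store, "visit_data")) == 0)
    }
  })
})

test_that("study states survive a save/load round trip", {
  state <- deployed_tiny_state()
  p <- include_participant(state, "muc", "doc")
  submit_entry(state, p$pid, "baseline",
               list(age = "44", sex = "f", pregnant = "true", dx = "J45.9"),
               "doc", complete = TRUE)
  submit_entry(state, p$pid, PARTICIPANT_VISIT, list(meds = "aspirin"), "doc")
  path <- tempfile(fileext = ".json")
  save_study(state, path)
  restored <- load_study(path)
  expect_identical(restored$mode, "deployment")
  expect_identical(restored$metadata, state$metadata)
  expect_identical(store_size(restored$store), store_size(state$store))
  expect_true(pid_exists(restored, p$pid))
  expect_identical(documentation_status(restored, p$pid),
                   documentation_status(state, p$pid))
  expect_identical(store_digest(restored$store), store_digest(state$store))
  # sequence continues correctly after reload
  expect_identical(include_participant(restored, "muc", "doc")$pid, "muc-0002")
})
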