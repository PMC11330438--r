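# builds a small FHIR R4 Questionnaire covering the mapping table
fhir_questionnaire <- function() {
  list(
    resourceType = "Questionnaire", title = "Screening",
    item = list(
      list(linkId = "Age", type = "integer", text = "Age in years",
           required = TRUE),
      list(linkId = "smoker", type = "boolean", text = "Current smoker"),
      list(linkId = "packs", type = "decimal", text = "Packs per day",
           enableWhen = list(list(question = "smoker", operator = "=",
                                  answerBoolean = TRUE))),
      list(linkId = "visitDate", type = "date", text = "Visit date"),
      list(linkId = "wakeTime", type = "time", text = "Waking time"),
      list(linkId = "notes", type = "text", text = "Notes"),
      list(linkId = "demo", type = "group", item = list(
        list(linkId = "sex", type = "choice", text = "Sex",
             answerOption = list(
               list(valueCoding = list(code = "f", display = "Female")),
               list(valueCoding = list(code = "m", display = "Male")))),
        list(linkId = "country", type = "choice", text = "Country",
             answerOption = lapply(1:9, function(i) {
               list(valueCoding = list(code = sprintf("c%02d", i),
                                       display = sprintf("Country %d", i)))
             })))),
      list(linkId = "dx", type = "open-choice", text = "Diagnosis",
           answerOption = list(
             list(valueCoding = list(code = "J45.9", display = "Asthma")),
             list(valueCoding = list(code = "I10", display = "Hypertension")))),
      list(linkId = "photo", type = "attachment", text = "Photo"),
      list(linkId = "info", type = "display", text = "Read this first"),
      list(linkId = "eitherOr", type = "text", text = "Either-or field",
           enableWhen = list(
             list(question = "smoker", operator = "=", answerBoolean = TRUE),
             list(question = "Age", operator = ">=", answerInteger = 65L)),
           enableBehavior = "any")
    )
  )
}

test_that("questionnaire items map onto the documented widget types", {
  out <- questionnaire_to_metadata(fhir_questionnaire())
  set <- out$set
  types <- vapply(set$widgets, function(w) w$input_type, character(1))
  names(types) <- vapply(set$widgets, function(w) w$variable_id, character(1))
  expect_identical(unname(types["age"]), "integer")
  expect_identical(unname(types["smoker"]), "checkbox")
  expect_identical(unname(types["packs"]), "float")
  expect_identical(unname(types["visitdate"]), "date")
  expect_identical(unname(types["waketime"]), "time")
  expect_identical(unname(types["notes"]), "text")
  # group flattening with dotted prefix, <= 7 options -> radio, more -> dropdown
  expect_identical(unname(types["demo_sex"]), "radio")
  expect_identical(unname(types["demo_country"]), "dropdown")
  # open-choice becomes a searchable dropdown over a generated lookup table
  expect_identical(unname(types["dx"]), "dropdown_search")
  expect_identical(length(set$lookup_tables), 1L)
  expect_true("J45.9" %in% set$lookup_tables[[1]]$entries$code)

  # enableWhen mapping
  w_packs <- set$widgets[[which(names(types) == "packs")]]
  expect_identical(serialize_condition(w_packs$condition), "smoker eq true")
  w_either <- set$widgets[[which(names(types) == "eitherOr" |
                                 names(types) == "eitheror")]]
  expect_identical(serialize_condition(w_either$condition),
                   "ANY(smoker eq true, age ge 65)")

  # required flag and report bookkeeping
  expect_true(set$widgets[[which(names(types) == "age")]]$required)
  skipped_ids <- vapply(out$report$items_skipped, function(s) s$linkId,
                        character(1))
  expect_true("photo" %in% skipped_ids)
  expect_true("info" %in% skipped_ids)
  expect_identical(out$report$items_mapped + length(out$report$items_skipped),
                   out$report$items_encountered)
  expect_true(length(out$report$warnings) > 0)  # 9-option radio note
})

test_that("mapping is deterministic and survives the metadata round trip", {
  json <- jsonlite::toJSON(fhir_questionnaire(), auto_unbox = TRUE)
  o1 <- questionnaire_to_metadata(as.character(json))
  o2 <- questionnaire_to_metadata(as.character(json))
  expect_identical(o1, o2)

  # import into a study, export, re-import: the mapped widgets survive
  study <- study_metadata("fhir_host",
                          visits = list(visit_definition("v1", order_index = 0L)))
  study <- import_variable_set(o1$set, study, "v1")
  expect_true(report_ok(validate_study_metadata(study)))
  back <- import_metadata(export_metadata(study,
                                          timestamp = "2024-06-01T00:00:00.000Z"))
  expect_identical(back, study)
})

test_that("non-questionnaires and malformed resources are rejected", {
  expect_edc_error(questionnaire_to_metadata(list(resourceType = "Patient")),
                   "NOT_A_QUESTIONNAIRE")
  expect_edc_error(questionnaire_to_metadata("{not json"),
                   "MALFORMED_RESOURCE")
  expect_edc_error(
    questionnaire_to_metadata(list(resourceType = "Questionnaire",
                                   item = list(list(type = "integer")))),
    "MALFORMED_RESOURCE")
})

fhir_response <- function(subject, age, sex, status = "completed") {
  list(resourceType = "QuestionnaireResponse", status = status,
       subject = list(reference = subject),
       item = list(
         list(linkId = "age", answer = list(list(valueInteger = age))),
         list(linkId = "sex", answer = list(list(valueCoding = list(code = sex)))),
         list(linkId = "dx", answer = list(list(valueCoding = list(code = "I10")))),
         list(linkId = "bogus", answer = list(list(valueString = "zzz")))))
}

test_that("responses become validated submissions through the normal path", {
  state <- deployed_tiny_state()
  p <- include_participant(state, "muc", "doc")
  bundle <- list(resourceType = "Bundle", entry = list(
    list(resource = fhir_response("Patient/1", 42L, "f"))))
  out <- responses_to_records(bundle, state, "baseline",
                              c("Patient/1" = p$pid))
  expect_identical(length(out$submissions), 1L)
  sub <- out$submissions[[1]]
  expect_identical(sub$values$age, "42")
  expect_true(sub$complete_flag)
  skip_reasons <- vapply(out$report$items_skipped, function(s) s$reason,
                         character(1))
  expect_true("UNKNOWN_LINKID" %in% skip_reasons)

  # a code outside the widget's choices is skipped with a reason
  bad <- fhir_response("Patient/1", 42L, "unknown_code")
  out2 <- responses_to_records(list(bad), state, "baseline",
                               c("Patient/1" = p$pid))
  expect_true("CODE_NOT_IN_CHOICES" %in%
                vapply(out2$report$items_skipped, function(s) s$reason,
                       character(1)))
  expect_null(out2$submissions[[1]]$values$sex)

  # the bridge writes nothing itself; apply_submissions goes through
  # submit_entry and the audit store
  n0 <- store_size(state$store)
  apply_submissions(state, out$submissions)
  expect_identical(store_size(state$store), n0 + 1L)
  row <- query_current(state$store, "visit_data")[[1]]
  expect_identical(row$payload$values$age, "42")

  expect_edc_error(
    responses_to_records(bundle, state, "baseline", c("Patient/9" = "x")),
    "UNKNOWN_PID")
  editor <- study_state(tiny_study())
  expect_edc_error(
    responses_to_records(bundle, editor, "baseline", c("Patient/1" = "x")),
    "NOT_DEPLOYED")
})

test_that("an imported response set yields complete documentation statuses", {
  state <- deployed_tiny_state()
  pid_map <- character(0)
  entries <- list()
  for (i in 1:20) {
    p <- include_participant(state, "muc", "doc")
    ref <- sprintf("Patient/%d", i)
    pid_map[ref] <- p$pid
    entries[[i]] <- list(resource = fhir_response(ref, 30L + i,
                                                  c("f", "m")[1 + i %% 2]))
  }
  bundle <- list(resourceType = "Bundle", entry = entries)
  out <- responses_to_records(bundle, state, "baseline", pid_map)
  apply_submissions(state, out$submissions)
  statuses <- vapply(unname(pid_map), function(pid) {
    df <- documentation_status(state, pid)
    df$status[df$visit_id == "baseline"]
  }, character(1))
  expect_identical(unname(statuses), rep("complete", 20))
})
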