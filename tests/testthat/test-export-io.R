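populated_state <- function(seed = 17, n = 12, widgets = 20) {
  cfg <- demo_config(seed = seed, n_participants = n, n_widgets = widgets)
  study <- generate_demo_metadata(cfg)
  sim <- simulate_entries(study, cfg)
  list(state = sim$state, study = study, cfg = cfg)
}

test_that("the codebook has one row per widget with serialized choices", {
  study <- tiny_study()
  cb <- build_codebook(study)
  expect_identical(nrow(cb), length(study$widgets))
  sex_row <- cb[cb$variable_id == "sex", ]
  expect_identical(sex_row$choices_serialized, "f=Female|m=Male")
  expect_identical(cb[cb$variable_id == "pregnant", ]$condition_serialized,
                   'sex eq "f"')
  expect_identical(cb[cb$variable_id == "meds", ]$visit_ids, "participant")

  for (seed in c(2, 9)) {
    px <- populated_state(seed = seed, n = 3)
    expect_identical(nrow(build_codebook(px$study)), length(px$study$widgets))
  }
})

test_that("visit tables carry current head values cell-for-cell", {
  px <- populated_state()
  state <- px$state
  for (v in px$study$visits) {
    tab <- export_visit_table(state$store, px$study, v$visit_id)
    heads <- Filter(function(r) identical(r$payload$visit_id, v$visit_id),
                    query_current(state$store, "visit_data"))
    expect_identical(nrow(tab), length(heads))
    for (r in heads) {
      row <- tab[tab$pid == r$payload$pid &
                 tab$visit_instance == as.character(r$payload$visit_instance), ]
      expect_identical(nrow(row), 1L)
      for (k in names(r$payload$values)) {
        expect_identical(row[[k]], as.character(r$payload$values[[k]]),
                         label = paste(r$payload$pid, k))
      }
      # all other variable columns are empty
      others <- setdiff(names(row), c("pid", "visit_instance",
                                      names(r$payload$values)))
      expect_true(all(row[others] == ""))
    }
  }
  expect_edc_error(export_visit_table(state$store, px$study, "ghost"),
                   "UNKNOWN_VISIT")
})

test_that("an undocumented study exports header-only tables", {
  state <- deployed_tiny_state()
  tab <- export_visit_table(state$store, state$metadata, "baseline")
  expect_identical(nrow(tab), 0L)
  expect_identical(names(tab), c("pid", "visit_instance", "age", "sex",
                                 "pregnant", "dx"))
})

test_that("aggregated export names columns by visit, instance and variable", {
  state <- deployed_tiny_state()
  p <- include_participant(state, "muc", "doc")
  submit_entry(state, p$pid, "baseline",
               list(age = "44", sex = "f", pregnant = "true", dx = "I10"),
               "doc")
  submit_entry(state, p$pid, "followup", list(note = "first"), "doc")
  submit_entry(state, p$pid, "followup", list(note = "second"), "doc",
               visit_instance = 2L)
  submit_entry(state, p$pid, PARTICIPANT_VISIT, list(meds = "aspirin"), "doc")

  agg <- export_aggregated(state$store, state$metadata)
  expect_identical(nrow(agg), 1L)
  expect_true(all(c("pid", "baseline.age", "baseline.sex",
                    "followup.1.note", "followup.2.note",
                    "participant.meds") %in% names(agg)))
  expect_identical(agg$`baseline.age`, "44")
  expect_identical(agg$`followup.2.note`, "second")
  expect_identical(agg$`participant.meds`, "aspirin")
})

test_that("aggregated cells match the per-visit tables after un-pivoting", {
  px <- populated_state(seed = 23)
  state <- px$state
  agg <- export_aggregated(state$store, px$study)
  for (v in px$study$visits) {
    tab <- export_visit_table(state$store, px$study, v$visit_id)
    for (i in seq_len(nrow(tab))) {
      inst <- as.integer(tab$visit_instance[i])
      for (k in setdiff(names(tab), c("pid", "visit_instance"))) {
        col <- if (v$repeating) paste(v$visit_id, inst, k, sep = ".")
          else paste(v$visit_id, k, sep = ".")
        expect_identical(agg[agg$pid == tab$pid[i], col][[1]], tab[i, k],
                         label = paste(tab$pid[i], col))
      }
    }
  }
})

test_that("export bundles have the documented layout and exact row counts", {
  px <- populated_state(seed = 29, n = 8)
  out <- write_bundle(px$state$store, px$study,
                      timestamp = "2024-06-01T00:00:00.000Z")
  expect_true(all(c("codebook.csv", "audit/audit_log.csv", "manifest.json",
                    "data/participants.csv", "data/aggregated_wide.csv",
                    "metadata/widgets.csv") %in% out$members))
  expect_true(length(out$members) >= 6)

  root <- tempfile()
  utils::unzip(out$path, exdir = root, unzip = "internal")
  manifest <- jsonlite::fromJSON(file.path(root, "manifest.json"),
                                 simplifyVector = FALSE)
  for (nm in names(manifest$members)) {
    cnt <- manifest$members[[nm]]
    if (is.null(cnt)) next
    got <- length(readLines(file.path(root, nm), warn = FALSE)) - 1L
    expect_identical(got, as.integer(cnt), label = nm)
  }
  # the bundled metadata reproduces the study metadata
  expect_identical(import_metadata(file.path(root, "metadata")), px$study)
})

test_that("bundle bytes are reproducible under an injected timestamp", {
  px <- populated_state(seed = 31, n = 5)
  p1 <- write_bundle(px$state$store, px$study, tempfile(fileext = ".zip"),
                     timestamp = "2024-06-01T00:00:00.000Z")$path
  p2 <- write_bundle(px$state$store, px$study, tempfile(fileext = ".zip"),
                     timestamp = "2024-06-01T00:00:00.000Z")$path
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("every data column resolves to a codebook row", {
  px <- populated_state(seed = 37, n = 4)
  cb <- build_codebook(px$study)
  agg <- export_aggregated(px$state$store, px$study)
  for (col in setdiff(names(agg), "pid")) {
    var <- sub("^[^.]+\\.([0-9]+\\.)?", "", col)
    expect_true(var %in% cb$variable_id, label = col)
  }
})

test_that("the XLSX writer produces a workbook openpyxl can read back", {
  df <- data.frame(pid = c("muc-0001", "muc-0002"),
                   note = c("says \"fine\", improving", "x <&> y"),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".xlsx")
  write_minimal_xlsx(df, path, timestamp = "2024-06-01T00:00:00.000Z")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, csv, openpyxl",
    "wb = openpyxl.load_workbook(sys.argv[1])",
    "ws = wb.active",
    "w = csv.writer(sys.stdout)",
    "for row in ws.iter_rows():",
    "    w.writerow(['' if c.value is None else c.value for c in row])"
  ), script)
  out <- system2("python", c(script, path), stdout = TRUE)
  back <- utils::read.csv(text = paste(out, collapse = "\n"),
                          colClasses = "character")
  expect_identical(back$pid, df$pid)
  expect_identical(back$note, df$note)
})
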