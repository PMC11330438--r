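METADATA_FORMAT_VERSION <- "1"

WIDGETS_CSV_COLS <- c("variable_id", "input_type", "label", "required",
                      "visit_ids", "lookup_table_id", "order_index", "units",
                      "help_text")
VISITS_CSV_COLS <- c("visit_id", "title", "order_index", "repeating", "mobile")
CHOICES_CSV_COLS <- c("variable_id", "code", "label", "choice_order")
CONDITIONS_CSV_COLS <- c("variable_id", "condition_serialized")

metadata_tables <- function(study) {
  visits <- data.frame(
    visit_id = vapply(study$visits, function(v) v$visit_id, character(1)),
    title = vapply(study$visits, function(v) v$title, character(1)),
    order_index = vapply(study$visits, function(v) as.character(v$order_index),
                         character(1)),
    repeating = vapply(study$visits, function(v) if (v$repeating) "true" else "false",
                       character(1)),
    mobile = vapply(study$visits, function(v) if (v$mobile) "true" else "false",
                    character(1)),
    stringsAsFactors = FALSE
  )
  if (length(study$visits) == 0) {
    visits <- data.frame(visit_id = character(), title = character(),
                         order_index = character(), repeating = character(),
                         mobile = character(), stringsAsFactors = FALSE)
  }

  ws <- study$widgets
  widgets <- data.frame(
    variable_id = vapply(ws, function(w) w$variable_id, character(1)),
    input_type = vapply(ws, function(w) w$input_type, character(1)),
    label = vapply(ws, function(w) w$label, character(1)),
    required = vapply(ws, function(w) if (w$required) "true" else "false",
                      character(1)),
    visit_ids = vapply(ws, function(w) paste(w$visit_ids, collapse = ";"),
                       character(1)),
    lookup_table_id = vapply(ws, function(w) null_to_blank(w$lookup_table_id),
                             character(1)),
    order_index = vapply(ws, function(w) as.character(w$order_index),
                         character(1)),
    units = vapply(ws, function(w) null_to_blank(w$units), character(1)),
    help_text = vapply(ws, function(w) null_to_blank(w$help_text), character(1)),
    stringsAsFactors = FALSE
  )
  if (length(ws) == 0) {
    widgets <- as.data.frame(stats::setNames(
      replicate(length(WIDGETS_CSV_COLS), character(), simplify = FALSE),
      WIDGETS_CSV_COLS), stringsAsFactors = FALSE)
  }

  choice_rows <- list()
  for (w in ws) {
    if (is.null(w$choices) || nrow(w$choices) == 0) next
    choice_rows[[length(choice_rows) + 1L]] <- data.frame(
      variable_id = w$variable_id, code = w$choices$code,
      label = w$choices$label,
      choice_order = as.character(seq_len(nrow(w$choices)) - 1L),
      stringsAsFactors = FALSE)
  }
  choices <- if (length(choice_rows) > 0) do.call(rbind, choice_rows) else
    as.data.frame(stats::setNames(
      replicate(length(CHOICES_CSV_COLS), character(), simplify = FALSE),
      CHOICES_CSV_COLS), stringsAsFactors = FALSE)
  rownames(choices) <- NULL

  cond_rows <- list()
  for (w in ws) {
    if (is.null(w$condition)) next
    cond_rows[[length(cond_rows) + 1L]] <- data.frame(
      variable_id = w$variable_id,
      condition_serialized = serialize_condition(w$condition),
      stringsAsFactors = FALSE)
  }
  conditions <- if (length(cond_rows) > 0) do.call(rbind, cond_rows) else
    as.data.frame(stats::setNames(
      replicate(length(CONDITIONS_CSV_COLS), character(), simplify = FALSE),
      CONDITIONS_CSV_COLS), stringsAsFactors = FALSE)
  rownames(conditions) <- NULL

  lookups <- lapply(study$lookup_tables, function(l) {
    data.frame(code = l$entries$code, label = l$entries$label,
               stringsAsFactors = FALSE)
  })
  names(lookups) <- lookup_ids_of(study)

  list(visits = visits, widgets = widgets, choices = choices,
       conditions = conditions, lookups = lookups)
}

metadata_manifest <- function(study, timestamp) {
  lut_names <- lapply(study$lookup_tables, function(l) l$name)
  names(lut_names) <- lookup_ids_of(study)
  list(study_id = study$study_id,
       title = study$title,
       metadata_version = study$metadata_version,
       format_version = METADATA_FORMAT_VERSION,
       created = timestamp,
       lookup_table_names = lut_names)
}

# the CSV members of a metadata bundle, as named text entries under `prefix`
metadata_bundle_members <- function(study, prefix = "") {
  tb <- metadata_tables(study)
  members <- list()
  members[[paste0(prefix, "visits.csv")]] <- csv_text(tb$visits)
  members[[paste0(prefix, "widgets.csv")]] <- csv_text(tb$widgets)
  members[[paste0(prefix, "choices.csv")]] <- csv_text(tb$choices)
  members[[paste0(prefix, "conditions.csv")]] <- csv_text(tb$conditions)
  for (lid in names(tb$lookups)) {
    members[[paste0(prefix, "lookup_tables/", lid, ".csv")]] <-
      csv_text(tb$lookups[[lid]])
  }
  members
}

manifest_json <- function(manifest) {
  # stable key order for byte determinism; newline-terminated text member
  paste0(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                       digits = NA, null = "null",
                                       pretty = TRUE)), "\n")
}

#' Export study metadata as a bundle (zip of CSV tables)
#'
#' The bundle contains `visits.csv`, `widgets.csv`, `choices.csv`,
#' `conditions.csv` (conditions in the canonical string form of
#' [serialize_condition()]), one `lookup_tables/<id>.csv` per lookup table,
#' and `manifest.json`. All CSVs are RFC 4180, UTF-8, LF, header row
#' mandatory; bundle bytes are identical across runs given identical
#' metadata and timestamp.
#'
#' @param study a valid `edc_study_metadata` (raises `INVALID_METADATA`
#'   otherwise).
#' @param path output file path (`.zip`); defaults to a tempfile.
#' @param timestamp injected UTC ISO 8601 creation timestamp; defaults to
#'   the current time.
#' @return the path, invisibly.
#' @export
export_metadata <- function(study, path = tempfile(fileext = ".zip"),
                            timestamp = system_clock()()) {
  rep <- validate_study_metadata(study)
  if (!report_ok(rep)) {
    edc_error("INVALID_METADATA", "study metadata fails validation",
              data = list(report = rep))
  }
  members <- metadata_bundle_members(study)
  members[["manifest.json"]] <- manifest_json(metadata_manifest(study, timestamp))
  members <- members[order(names(members))]
  zip_write(path, members, timestamp)
  invisible(path)
}

require_cols <- function(df, cols, table) {
  if (!identical(names(df), cols)) {
    edc_error("MALFORMED_BUNDLE",
              sprintf("%s has header [%s], expected [%s]", table,
                      paste(names(df), collapse = ","),
                      paste(cols, collapse = ",")))
  }
  df
}

#' Import a metadata bundle
#'
#' Reconstructs the `edc_study_metadata` from a bundle written by
#' [export_metadata()] (round-trip identity, timestamps aside). Used to
#' clone an existing study exactly or to upload previously developed
#' definitions.
#'
#' @param path path to the bundle zip, or to an unpacked bundle directory.
#' @return an `edc_study_metadata`.
#' @export
import_metadata <- function(path) {
  if (dir.exists(path)) {
    root <- path
  } else {
    root <- tempfile("metadata_bundle_")
    zip_extract(path, root)
  }
  man_path <- file.path(root, "manifest.json")
  if (!file.exists(man_path)) {
    edc_error("MALFORMED_BUNDLE", "manifest.json is missing")
  }
  manifest <- jsonlite::fromJSON(man_path, simplifyVector = FALSE)
  if (!identical(as.character(manifest$format_version %||% ""),
                 METADATA_FORMAT_VERSION)) {
    edc_error("UNSUPPORTED_FORMAT_VERSION",
              sprintf("bundle format '%s' is not supported",
                      manifest$format_version %||% "?"))
  }
  for (f in c("visits.csv", "widgets.csv", "choices.csv", "conditions.csv")) {
    if (!file.exists(file.path(root, f))) {
      edc_error("MALFORMED_BUNDLE", sprintf("%s is missing", f))
    }
  }
  visits_df <- require_cols(read_csv_strict(file.path(root, "visits.csv")),
                            VISITS_CSV_COLS, "visits.csv")
  widgets_df <- require_cols(read_csv_strict(file.path(root, "widgets.csv")),
                             WIDGETS_CSV_COLS, "widgets.csv")
  choices_df <- require_cols(read_csv_strict(file.path(root, "choices.csv")),
                             CHOICES_CSV_COLS, "choices.csv")
  cond_df <- require_cols(read_csv_strict(file.path(root, "conditions.csv")),
                          CONDITIONS_CSV_COLS, "conditions.csv")

  lut_dir <- file.path(root, "lookup_tables")
  lut_names <- manifest$lookup_table_names %||% list()
  # table order follows the manifest, preserving round-trip identity
  lut_ids <- names(lut_names)
  if (length(lut_ids) == 0 && dir.exists(lut_dir)) {
    lut_ids <- sub("\\.csv$", "", sort(list.files(lut_dir, pattern = "\\.csv$")))
  }
  lookup_tables <- lapply(lut_ids, function(lid) {
    f <- file.path(lut_dir, paste0(lid, ".csv"))
    if (!file.exists(f)) {
      edc_error("MALFORMED_BUNDLE",
                sprintf("lookup_tables/%s.csv is missing", lid))
    }
    df <- read_csv_strict(f)
    if (!identical(names(df), c("code", "label"))) {
      edc_error("MALFORMED_BUNDLE",
                sprintf("lookup_tables/%s.csv has a bad header", lid))
    }
    lookup_table(lid, as.character(lut_names[[lid]] %||% lid), df)
  })

  visits <- lapply(seq_len(nrow(visits_df)), function(i) {
    r <- visits_df[i, ]
    visit_definition(r$visit_id, r$title, as.integer(r$order_index),
                     repeating = isTRUE(as_flag(r$repeating)),
                     mobile = isTRUE(as_flag(r$mobile)))
  })

  cond_map <- stats::setNames(as.list(cond_df$condition_serialized),
                              cond_df$variable_id)
  widgets <- lapply(seq_len(nrow(widgets_df)), function(i) {
    r <- widgets_df[i, ]
    ch <- choices_df[choices_df$variable_id == r$variable_id, , drop = FALSE]
    ch <- if (nrow(ch) > 0) {
      ch <- ch[order(as.integer(ch$choice_order)), , drop = FALSE]
      data.frame(code = ch$code, label = ch$label, stringsAsFactors = FALSE)
    } else NULL
    vis <- if (nzchar(r$visit_ids)) strsplit(r$visit_ids, ";", fixed = TRUE)[[1]]
           else character(0)
    cond <- cond_map[[r$variable_id]]
    widget_definition(
      r$variable_id, r$input_type, r$label,
      required = isTRUE(as_flag(r$required)),
      visit_ids = vis,
      choices = ch,
      lookup_table_id = blank_to_null(r$lookup_table_id),
      condition = if (!is.null(cond)) parse_condition(cond) else NULL,
      order_index = as.integer(r$order_index),
      units = blank_to_null(r$units),
      help_text = blank_to_null(r$help_text)
    )
  })

  study <- study_metadata(
    study_id = as.character(manifest$study_id),
    title = as.character(manifest$title %||% manifest$study_id),
    visits = visits, widgets = widgets, lookup_tables = lookup_tables,
    metadata_version = as.integer(manifest$metadata_version %||% 1L)
  )
  rep <- validate_study_metadata(study)
  if (!report_ok(rep)) {
    edc_error("INVALID_METADATA", "imported metadata fails validation",
              data = list(report = rep))
  }
  study
}
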