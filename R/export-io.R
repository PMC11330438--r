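#' Auto-generate the study codebook
#'
#' One row per widget, ordered by (visit order, `order_index`) with
#' participant-centered widgets last: variable id, visit assignment, label,
#' type, requiredness, the display condition in canonical string form, the
#' choice list serialized `code=label|code=label`, lookup reference, units
#' and order index. The codebook is the data dictionary shipped with every
#' export.
#'
#' @param metadata a valid `edc_study_metadata`.
#' @return a data frame of class `edc_codebook`.
#' @export
build_codebook <- function(metadata) {
  rep <- validate_study_metadata(metadata)
  if (!report_ok(rep)) {
    edc_error("INVALID_METADATA", "metadata fails validation",
              data = list(report = rep))
  }
  visit_order <- stats::setNames(
    vapply(metadata$visits, function(v) v$order_index, integer(1)),
    visit_ids_of(metadata))
  ws <- metadata$widgets
  first_visit_rank <- vapply(ws, function(w) {
    if (length(w$visit_ids) == 0) .Machine$integer.max
    else min(visit_order[w$visit_ids])
  }, numeric(1))
  ord <- order(first_visit_rank,
               vapply(ws, function(w) w$order_index, integer(1)))
  ws <- ws[ord]
  df <- data.frame(
    variable_id = vapply(ws, function(w) w$variable_id, character(1)),
    visit_ids = vapply(ws, function(w) {
      if (length(w$visit_ids) == 0) PARTICIPANT_VISIT
      else paste(w$visit_ids, collapse = ";")
    }, character(1)),
    label = vapply(ws, function(w) w$label, character(1)),
    input_type = vapply(ws, function(w) w$input_type, character(1)),
    required = vapply(ws, function(w) if (w$required) "true" else "false",
                      character(1)),
    condition_serialized = vapply(ws, function(w) serialize_condition(w$condition),
                                  character(1)),
    choices_serialized = vapply(ws, function(w) {
      if (is.null(w$choices)) "" else
        paste(paste0(w$choices$code, "=", w$choices$label), collapse = "|")
    }, character(1)),
    lookup_table_id = vapply(ws, function(w) null_to_blank(w$lookup_table_id),
                             character(1)),
    units = vapply(ws, function(w) null_to_blank(w$units), character(1)),
    order_index = vapply(ws, function(w) as.character(w$order_index),
                         character(1)),
    stringsAsFactors = FALSE
  )
  if (length(ws) == 0) {
    df <- as.data.frame(stats::setNames(
      replicate(10, character(), simplify = FALSE),
      c("variable_id", "visit_ids", "label", "input_type", "required",
        "condition_serialized", "choices_serialized", "lookup_table_id",
        "units", "order_index")), stringsAsFactors = FALSE)
  }
  class(df) <- c("edc_codebook", "data.frame")
  df
}

# current visit_data heads grouped as (pid, visit_id, instance) -> values
current_entries <- function(store) {
  heads <- query_current(store, entity = "visit_data")
  lapply(unname(heads), function(row) row$payload)
}

#' Per-visit data table
#'
#' One row per (participant, visit instance) holding the current head
#' values; columns are `pid`, `visit_instance`, then the visit's variable
#' ids in `order_index` order. Missing values are empty strings. Rows are
#' sorted by (pid, instance) for reproducibility.
#'
#' @param store the audit store holding the clinical rows.
#' @param metadata the study metadata.
#' @param visit_id a defined visit id or [PARTICIPANT_VISIT].
#' @return a character data frame.
#' @export
export_visit_table <- function(store, metadata, visit_id) {
  if (!identical(visit_id, PARTICIPANT_VISIT) &&
      is.null(find_visit(metadata, visit_id))) {
    edc_error("UNKNOWN_VISIT", sprintf("visit '%s' is not defined", visit_id))
  }
  widgets <- widgets_for_visit(metadata, visit_id)
  var_ids <- vapply(widgets, function(w) w$variable_id, character(1))
  entries <- Filter(function(p) identical(p$visit_id, visit_id),
                    current_entries(store))
  cols <- c("pid", "visit_instance", var_ids)
  if (length(entries) == 0) {
    df <- as.data.frame(stats::setNames(
      replicate(length(cols), character(), simplify = FALSE), cols),
      stringsAsFactors = FALSE)
    return(df)
  }
  ord <- order(vapply(entries, function(p) p$pid, character(1)),
               vapply(entries, function(p) p$visit_instance, integer(1)))
  entries <- entries[ord]
  rows <- lapply(entries, function(p) {
    vals <- vapply(var_ids, function(k) {
      v <- p$values[[k]]
      if (is.null(v)) "" else as.character(v)
    }, character(1))
    c(pid = p$pid, visit_instance = as.character(p$visit_instance), vals)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  rownames(df) <- NULL
  df
}

#' Participant registry table
#'
#' One row per currently included participant: `pid`, `site`, `included_at`.
#'
#' @inheritParams export_visit_table
#' @export
export_participants <- function(store) {
  heads <- query_current(store, entity = "participant")
  if (length(heads) == 0) {
    return(data.frame(pid = character(), site = character(),
                      included_at = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    pid = vapply(unname(heads), function(r) r$payload$pid, character(1)),
    site = vapply(unname(heads), function(r) r$payload$site, character(1)),
    included_at = vapply(unname(heads), function(r) {
      # inclusion time is the first version's timestamp
      r$timestamp
    }, character(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$pid), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Aggregated wide table over all visits
#'
#' One row per participant. Columns are named `<visit_id>.<variable_id>`
#' for non-repeating visits, `<visit_id>.<k>.<variable_id>` for the k-th
#' instance of a repeating visit (k counted from 1 in chronological order
#' of first submission), and `participant.<variable_id>` for
#' participant-centered variables.
#'
#' @inheritParams export_visit_table
#' @return a character data frame, one row per included participant.
#' @export
export_aggregated <- function(store, metadata) {
  participants <- export_participants(store)
  entries <- current_entries(store)

  # instance counts per repeating visit, ordered chronologically by the
  # record's first version timestamp (instance numbers are assigned at
  # entry time and already chronological per participant)
  max_inst <- list()
  for (p in entries) {
    vid <- p$visit_id
    cur <- max_inst[[vid]] %||% 0L
    if (p$visit_instance > cur) max_inst[[vid]] <- p$visit_instance
  }

  visits <- metadata$visits
  visits <- visits[order(vapply(visits, function(v) v$order_index, integer(1)))]
  col_spec <- list()  # list of (colname, visit_id, instance, variable_id)
  for (v in visits) {
    widgets <- widgets_for_visit(metadata, v$visit_id)
    insts <- if (v$repeating) seq_len(max(1L, max_inst[[v$visit_id]] %||% 1L))
             else 1L
    for (k in insts) {
      for (w in widgets) {
        nm <- if (v$repeating) {
          paste(v$visit_id, k, w$variable_id, sep = ".")
        } else paste(v$visit_id, w$variable_id, sep = ".")
        col_spec[[length(col_spec) + 1L]] <-
          list(nm = nm, visit = v$visit_id, inst = k, var = w$variable_id)
      }
    }
  }
  for (w in widgets_for_visit(metadata, PARTICIPANT_VISIT)) {
    col_spec[[length(col_spec) + 1L]] <-
      list(nm = paste(PARTICIPANT_VISIT, w$variable_id, sep = "."),
           visit = PARTICIPANT_VISIT, inst = 1L, var = w$variable_id)
  }

  col_names <- vapply(col_spec, function(s) s$nm, character(1))
  pids <- participants$pid
  if (length(pids) == 0) {
    df <- as.data.frame(stats::setNames(
      replicate(1 + length(col_names), character(), simplify = FALSE),
      c("pid", col_names)), stringsAsFactors = FALSE)
    return(df)
  }

  # index entries by (pid, visit, instance)
  ekey <- function(pid, visit, inst) paste(pid, visit, inst, sep = "\x1f")
  emap <- new.env(parent = emptyenv())
  for (p in entries) {
    emap[[ekey(p$pid, p$visit_id, p$visit_instance)]] <- p$values
  }

  mat <- matrix("", nrow = length(pids), ncol = length(col_names),
                dimnames = list(NULL, col_names))
  for (i in seq_along(pids)) {
    for (j in seq_along(col_spec)) {
      s <- col_spec[[j]]
      vals <- emap[[ekey(pids[i], s$visit, s$inst)]]
      if (!is.null(vals)) {
        v <- vals[[s$var]]
        if (!is.null(v)) mat[i, j] <- as.character(v)
      }
    }
  }
  df <- data.frame(pid = pids, mat, stringsAsFactors = FALSE,
                   check.names = FALSE)
  rownames(df) <- NULL
  df
}

# ---- minimal XLSX writer ----------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

#' Write a data frame as a minimal XLSX workbook
#'
#' A single-sheet OOXML spreadsheet with all cells as inline strings —
#' sufficient for handing the aggregated dataset to spreadsheet users. CSV
#' remains the canonical, information-preserving format.
#'
#' @param df a data frame (values written as character).
#' @param path output `.xlsx` path.
#' @param sheet sheet name.
#' @param timestamp injected timestamp for byte-reproducible output.
#' @return the path, invisibly.
#' @export
write_minimal_xlsx <- function(df, path, sheet = "data",
                               timestamp = system_clock()()) {
  letters_cache <- vapply(seq_len(max(1, ncol(df))), col_letter, character(1))
  cell <- function(i, j, v) {
    sprintf('<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            letters_cache[j], i, xml_escape(enc2utf8(as.character(v))))
  }
  rows <- character(nrow(df) + 1)
  header_cells <- vapply(seq_len(ncol(df)), function(j) cell(1, j, names(df)[j]),
                         character(1))
  rows[1] <- sprintf('<row r="1">%s</row>', paste(header_cells, collapse = ""))
  if (nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      cells <- vapply(seq_len(ncol(df)), function(j) {
        v <- df[i, j]
        if (is.na(v) || !nzchar(v)) "" else cell(i + 1, j, v)
      }, character(1))
      rows[i + 1] <- sprintf('<row r="%d">%s</row>', i + 1,
                             paste(cells, collapse = ""))
    }
  }
  sheet_xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
  workbook_xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="', xml_escape(sheet), '" sheetId="1" r:id="rId1"/></sheets>',
    '</workbook>')
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
    'Target="worksheets/sheet1.xml"/></Relationships>')
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" ',
    'Target="xl/workbook.xml"/></Relationships>')
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ',
    'ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ',
    'ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>')
  members <- list(
    "[Content_Types].xml" = content_types,
    "_rels/.rels" = root_rels,
    "xl/workbook.xml" = workbook_xml,
    "xl/_rels/workbook.xml.rels" = wb_rels,
    "xl/worksheets/sheet1.xml" = sheet_xml
  )
  zip_write(path, members, timestamp)
  invisible(path)
}

# ---- complete export bundle -------------------------------------------------

#' Write the complete study export bundle
#'
#' The downloadable zip artifact of a study:
#'
#' ```
#' data/participants.csv        participant registry
#' data/<visit_id>.csv          one table per visit (+ participant.csv)
#' data/aggregated_wide.csv     one row per participant over all visits
#' metadata/...                 the metadata bundle tables
#' codebook.csv                 auto-generated data dictionary
#' audit/audit_log.csv          the complete append-only audit trail
#' manifest.json                member list with data-row counts
#' ```
#'
#' Deleted records appear only in the audit log. Output bytes are identical
#' across runs given an identical store and injected timestamp.
#'
#' @param store the clinical audit store (e.g. `state$store`).
#' @param metadata the study metadata.
#' @param path output `.zip` path.
#' @param timestamp injected UTC ISO 8601 creation timestamp.
#' @return invisibly, a list with `path`, `members` and the manifest.
#' @export
write_bundle <- function(store, metadata, path = tempfile(fileext = ".zip"),
                         timestamp = system_clock()()) {
  tables <- list()
  tables[["data/participants.csv"]] <- export_participants(store)
  for (v in metadata$visits) {
    tables[[paste0("data/", v$visit_id, ".csv")]] <-
      export_visit_table(store, metadata, v$visit_id)
  }
  if (length(widgets_for_visit(metadata, PARTICIPANT_VISIT)) > 0) {
    tables[[paste0("data/", PARTICIPANT_VISIT, ".csv")]] <-
      export_visit_table(store, metadata, PARTICIPANT_VISIT)
  }
  tables[["data/aggregated_wide.csv"]] <- export_aggregated(store, metadata)
  tables[["codebook.csv"]] <- build_codebook(metadata)
  tables[["audit/audit_log.csv"]] <- audit_log_frame(store)

  members <- lapply(tables, csv_text)
  members <- c(members, metadata_bundle_members(metadata, prefix = "metadata/"))
  members[["metadata/manifest.json"]] <-
    manifest_json(metadata_manifest(metadata, timestamp))

  # every member with its data-row count (CSV: lines minus header)
  csv_rows <- function(nm) {
    if (!grepl("\\.csv$", nm)) return(NULL)
    lengths(regmatches(members[[nm]], gregexpr("\n", members[[nm]]))) - 1L
  }
  row_counts <- lapply(stats::setNames(names(members), names(members)), csv_rows)
  manifest <- list(
    study_id = metadata$study_id,
    metadata_version = metadata$metadata_version,
    format_version = METADATA_FORMAT_VERSION,
    created = timestamp,
    members = row_counts[order(names(row_counts))]
  )
  members[["manifest.json"]] <- manifest_json(manifest)
  members <- members[order(names(members))]
  zip_write(path, members, timestamp)
  invisible(list(path = path, members = names(members), manifest = manifest))
}
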