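STATE_FORMAT_VERSION <- "1"

widget_to_list <- function(w) {
  list(variable_id = w$variable_id, input_type = w$input_type,
       label = w$label, required = w$required,
       visit_ids = as.list(w$visit_ids),
       choices = if (is.null(w$choices)) NULL else
         lapply(seq_len(nrow(w$choices)), function(i) {
           list(code = w$choices$code[i], label = w$choices$label[i])
         }),
       lookup_table_id = w$lookup_table_id,
       condition = if (is.null(w$condition)) NULL else
         serialize_condition(w$condition),
       order_index = w$order_index, units = w$units, help_text = w$help_text)
}

widget_from_list <- function(x) {
  choices <- if (is.null(x$choices)) NULL else
    lapply(x$choices, function(c2) c(c2$code, c2$label))
  widget_definition(x$variable_id, x$input_type, x$label,
                    required = isTRUE(x$required),
                    visit_ids = unlist(x$visit_ids) %||% character(0),
                    choices = choices,
                    lookup_table_id = x$lookup_table_id,
                    condition = if (!is.null(x$condition))
                      parse_condition(x$condition),
                    order_index = as.integer(x$order_index),
                    units = x$units, help_text = x$help_text)
}

metadata_to_list <- function(m) {
  list(study_id = m$study_id, title = m$title,
       visits = lapply(m$visits, function(v) {
         list(visit_id = v$visit_id, title = v$title,
              order_index = v$order_index, repeating = v$repeating,
              mobile = v$mobile)
       }),
       widgets = lapply(m$widgets, widget_to_list),
       lookup_tables = lapply(m$lookup_tables, function(l) {
         list(lookup_table_id = l$lookup_table_id, name = l$name,
              entries = lapply(seq_len(nrow(l$entries)), function(i) {
                list(code = l$entries$code[i], label = l$entries$label[i])
              }))
       }),
       metadata_version = m$metadata_version)
}

metadata_from_list <- function(x) {
  study_metadata(
    study_id = x$study_id, title = x$title,
    visits = lapply(x$visits, function(v) {
      visit_definition(v$visit_id, v$title, as.integer(v$order_index),
                       repeating = isTRUE(v$repeating),
                       mobile = isTRUE(v$mobile))
    }),
    widgets = lapply(x$widgets, widget_from_list),
    lookup_tables = lapply(x$lookup_tables, function(l) {
      lookup_table(l$lookup_table_id, l$name,
                   lapply(l$entries, function(e) c(e$code, e$label)))
    }),
    metadata_version = as.integer(x$metadata_version)
  )
}

row_to_list <- function(r) {
  list(record_id = r$record_id, entity = r$entity, payload = r$payload,
       version_no = r$version_no, origin_id = r$origin_id, actor = r$actor,
       timestamp = r$timestamp, deleted = r$deleted,
       supersedes = r$supersedes)
}

row_from_list <- function(x) {
  payload <- x$payload
  # visit_instance arrives as numeric from JSON; normalize
  if (!is.null(payload$visit_instance)) {
    payload$visit_instance <- as.integer(payload$visit_instance)
  }
  list(row_seq = NA_integer_, record_id = x$record_id, entity = x$entity,
       payload = payload, payload_json = canonical_json(payload),
       version_no = as.integer(x$version_no), origin_id = x$origin_id,
       actor = x$actor, timestamp = x$timestamp, deleted = isTRUE(x$deleted),
       supersedes = if (is.null(x$supersedes)) NULL else
         list(record_id = x$supersedes$record_id,
              version_no = as.integer(x$supersedes$version_no)))
}

#' Save a study state to a JSON project file
#'
#' Serializes metadata, lifecycle state and both audit stores (permanent
#' and preview) to a single plain-text JSON file; [load_study()] restores
#' an equivalent state. This is the on-disk form used by the command-line
#' interface and by offline-device exchanges.
#'
#' @param state an `edc_study_state`.
#' @param path output path (`.json`).
#' @return the path, invisibly.
#' @export
save_study <- function(state, path) {
  doc <- list(
    format_version = STATE_FORMAT_VERSION,
    study_id = state$study_id,
    mode = state$mode,
    origin_id = state$origin_id,
    deployed_at = state$deployed_at,
    frozen_visits = as.list(state$frozen_visits),
    frozen_widgets = as.list(state$frozen_widgets),
    metadata = metadata_to_list(state$metadata),
    store_rows = lapply(store_rows(state$store), row_to_list),
    preview_rows = lapply(store_rows(state$preview_store), row_to_list),
    events = state$events
  )
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             path, useBytes = TRUE)
  invisible(path)
}

rebuild_indexes <- function(state) {
  for (row in query_current(state$store, entity = "participant")) {
    pid <- row$payload$pid
    site <- row$payload$site
    state$participants[[pid]] <- row$record_id
    seq_no <- suppressWarnings(as.integer(sub("^.*-", "", pid)))
    if (!is.na(seq_no)) {
      state$site_seq[[site]] <- max(state$site_seq[[site]] %||% 0L, seq_no)
    }
  }
  # include soft-deleted participants in the pid index so pid_exists can
  # answer FALSE through head inspection rather than absence
  for (rid in ls(state$store$index)) {
    head <- record_head(state$store, rid)
    if (head$entity == "participant" && head$deleted) {
      state$participants[[head$payload$pid]] <- rid
    }
  }
  for (st in list(state$store, state$preview_store)) {
    for (rid in ls(st$index)) {
      head <- record_head(st, rid)
      if (head$entity != "visit_data") next
      p <- head$payload
      state$entry_index[[entry_key(p$pid, p$visit_id, p$visit_instance)]] <- rid
    }
  }
  invisible(state)
}

#' Load a study state from a JSON project file
#'
#' @param path path written by [save_study()].
#' @param clock timestamp source for subsequent operations.
#' @return an `edc_study_state`.
#' @export
load_study <- function(path, clock = system_clock()) {
  if (!file.exists(path)) {
    edc_error("NO_PROJECT", sprintf("no study file at '%s'", path))
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(as.character(doc$format_version %||% ""),
                 STATE_FORMAT_VERSION)) {
    edc_error("UNSUPPORTED_FORMAT_VERSION",
              sprintf("study file format '%s' is not supported",
                      doc$format_version %||% "?"))
  }
  metadata <- metadata_from_list(doc$metadata)
  state <- study_state(metadata, origin_id = doc$origin_id %||% "local",
                       clock = clock)
  state$mode <- doc$mode %||% "editor"
  state$deployed_at <- doc$deployed_at
  state$frozen_visits <- unlist(doc$frozen_visits) %||% character(0)
  state$frozen_widgets <- unlist(doc$frozen_widgets) %||% character(0)
  state$events <- doc$events %||% list()
  for (x in doc$store_rows %||% list()) {
    append_row_raw(state$store, row_from_list(x))
  }
  for (x in doc$preview_rows %||% list()) {
    append_row_raw(state$preview_store, row_from_list(x))
  }
  state$store$study_id <- state$study_id
  state$store$metadata_version <-
    if (!is.null(state$deployed_at)) metadata$metadata_version
  rebuild_indexes(state)
  state
}
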