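#' Create a study state
#'
#' The study state ties metadata, lifecycle mode and the audit stores
#' together. A study starts in *editor* mode, where metadata is authored and
#' entry forms can be previewed against a transient store. Activating
#' deployment freezes the existing visit definitions, purges the preview
#' store and opens permanent data capture; only in deployment mode is
#' clinical data recorded permanently.
#'
#' The returned object has reference semantics (an environment): lifecycle
#' operations mutate it in place and return it invisibly.
#'
#' @param metadata an `edc_study_metadata`.
#' @param origin_id device/site token for rows written by this instance.
#' @param clock timestamp source shared by the stores.
#' @return an environment of class `edc_study_state`.
#' @export
study_state <- function(metadata, origin_id = "local",
                        clock = system_clock()) {
  stopifnot(inherits(metadata, "edc_study_metadata"))
  state <- new.env(parent = emptyenv())
  state$study_id <- metadata$study_id
  state$metadata <- metadata
  state$mode <- "editor"
  state$clock <- clock
  state$origin_id <- origin_id
  state$store <- audit_store(origin_id = origin_id, clock = clock,
                             study_id = metadata$study_id)
  state$preview_store <- audit_store(origin_id = origin_id, clock = clock,
                                     study_id = metadata$study_id)
  state$frozen_visits <- character(0)
  state$frozen_widgets <- character(0)
  state$deployed_at <- NULL
  state$participants <- new.env(parent = emptyenv())   # pid -> record_id
  state$site_seq <- new.env(parent = emptyenv())       # site -> max seq
  state$entry_index <- new.env(parent = emptyenv())    # pid|visit|inst -> record_id
  state$events <- list()
  class(state) <- "edc_study_state"
  state
}

#' @export
print.edc_study_state <- function(x, ...) {
  cat(sprintf("<study state %s: %s mode, %d participants, %d clinical rows>\n",
              x$study_id, x$mode, length(ls(x$participants)), x$store$n))
  invisible(x)
}

log_state_event <- function(state, code, message) {
  state$events[[length(state$events) + 1L]] <-
    list(code = code, message = message, at = state$clock())
  invisible(state)
}

active_store <- function(state) {
  if (state$mode == "deployment") state$store else state$preview_store
}

require_editor <- function(state) {
  if (state$mode != "editor") {
    edc_error("STUDY_NOT_IN_EDITOR_MODE",
              "metadata can only be changed in editor mode")
  }
}

bump_metadata_version <- function(state) {
  state$metadata$metadata_version <- state$metadata$metadata_version + 1L
}

# ---- editor operations ------------------------------------------------------

#' Edit study metadata in editor mode
#'
#' `add_visit()`, `edit_visit()` and `remove_visit()` manage visit
#' definitions; `add_widget()`, `update_widget()` and `remove_widget()`
#' manage widgets; `add_lookup_table()` uploads a vocabulary. All require
#' editor mode and bump `metadata_version`.
#'
#' Visits that existed at a deployment activation are frozen: editing or
#' removing them raises `VISIT_FROZEN` even after an admin reversal to
#' editor mode. After a reversal only additive changes are accepted —
#' narrowing changes to frozen widgets (removing them, changing their type,
#' dropping choices, making an optional field required) raise
#' `NARROWING_CHANGE`, which operationalizes database-integrity protection.
#'
#' @param state an `edc_study_state`.
#' @param visit an `edc_visit`.
#' @param widget an `edc_widget`.
#' @param lookup an `edc_lookup`.
#' @param variable_id id of the widget to remove.
#' @return the state, invisibly.
#' @name editor_ops
NULL

#' @rdname editor_ops
#' @export
add_visit <- function(state, visit) {
  require_editor(state)
  stopifnot(inherits(visit, "edc_visit"))
  if (!is.null(find_visit(state$metadata, visit$visit_id))) {
    edc_error("DUPLICATE_VISIT_ID",
              sprintf("visit '%s' already exists", visit$visit_id))
  }
  state$metadata$visits <- c(state$metadata$visits, list(visit))
  bump_metadata_version(state)
  invisible(state)
}

#' @rdname editor_ops
#' @export
edit_visit <- function(state, visit) {
  require_editor(state)
  stopifnot(inherits(visit, "edc_visit"))
  if (visit$visit_id %in% state$frozen_visits) {
    edc_error("VISIT_FROZEN",
              sprintf("visit '%s' was deployed and cannot be changed", visit$visit_id))
  }
  idx <- which(visit_ids_of(state$metadata) == visit$visit_id)
  if (length(idx) == 0) {
    edc_error("UNKNOWN_VISIT", sprintf("visit '%s' is not defined", visit$visit_id))
  }
  state$metadata$visits[[idx[1]]] <- visit
  bump_metadata_version(state)
  invisible(state)
}

#' @rdname editor_ops
#' @export
remove_visit <- function(state, visit_id) {
  require_editor(state)
  if (visit_id %in% state$frozen_visits) {
    edc_error("VISIT_FROZEN",
              sprintf("visit '%s' was deployed and cannot be removed", visit_id))
  }
  idx <- which(visit_ids_of(state$metadata) == visit_id)
  if (length(idx) == 0) {
    edc_error("UNKNOWN_VISIT", sprintf("visit '%s' is not defined", visit_id))
  }
  state$metadata$visits[[idx[1]]] <- NULL
  state$metadata$widgets <- lapply(state$metadata$widgets, function(w) {
    w$visit_ids <- setdiff(w$visit_ids, visit_id)
    w
  })
  bump_metadata_version(state)
  invisible(state)
}

#' @rdname editor_ops
#' @export
add_widget <- function(state, widget) {
  require_editor(state)
  stopifnot(inherits(widget, "edc_widget"))
  rep <- validate_widget_definition(widget, state$metadata)
  if (!is.null(find_widget(state$metadata, widget$variable_id))) {
    edc_error("DUPLICATE_ID",
              sprintf("variable '%s' already exists", widget$variable_id))
  }
  if (!report_ok(rep)) {
    edc_error("INVALID_WIDGET", "widget fails validation",
              data = list(report = rep))
  }
  state$metadata$widgets <- c(state$metadata$widgets, list(widget))
  bump_metadata_version(state)
  invisible(state)
}

# changes allowed on a frozen widget: label/help/units edits, added choices,
# relaxing requiredness, added visit assignments
narrowing_change <- function(old, new) {
  if (!identical(old$input_type, new$input_type)) return("input type changed")
  if (!identical(old$lookup_table_id, new$lookup_table_id)) {
    return("lookup table reference changed")
  }
  if (old$required == FALSE && new$required == TRUE) {
    return("optional field made required")
  }
  if (!is.null(old$choices)) {
    if (is.null(new$choices) || !all(old$choices$code %in% new$choices$code)) {
      return("choice codes removed")
    }
  }
  if (!all(old$visit_ids %in% new$visit_ids)) return("visit assignment removed")
  NULL
}

#' @rdname editor_ops
#' @export
update_widget <- function(state, widget) {
  require_editor(state)
  stopifnot(inherits(widget, "edc_widget"))
  idx <- which(widget_ids(state$metadata) == widget$variable_id)
  if (length(idx) == 0) {
    edc_error("UNKNOWN_VARIABLE",
              sprintf("variable '%s' is not defined", widget$variable_id))
  }
  old <- state$metadata$widgets[[idx[1]]]
  if (widget$variable_id %in% state$frozen_widgets) {
    prob <- narrowing_change(old, widget)
    if (!is.null(prob)) {
      edc_error("NARROWING_CHANGE",
                sprintf("widget '%s' was deployed; %s", widget$variable_id, prob))
    }
  }
  candidate <- state$metadata
  candidate$widgets[[idx[1]]] <- widget
  rep <- validate_study_metadata(candidate)
  if (!report_ok(rep)) {
    edc_error("INVALID_WIDGET", "widget update fails validation",
              data = list(report = rep))
  }
  state$metadata <- candidate
  bump_metadata_version(state)
  invisible(state)
}

#' @rdname editor_ops
#' @export
remove_widget <- function(state, variable_id) {
  require_editor(state)
  idx <- which(widget_ids(state$metadata) == variable_id)
  if (length(idx) == 0) {
    edc_error("UNKNOWN_VARIABLE", sprintf("variable '%s' is not defined", variable_id))
  }
  if (variable_id %in% state$frozen_widgets) {
    edc_error("NARROWING_CHANGE",
              sprintf("widget '%s' was deployed and cannot be removed", variable_id))
  }
  state$metadata$widgets[[idx[1]]] <- NULL
  bump_metadata_version(state)
  invisible(state)
}

#' @rdname editor_ops
#' @export
add_lookup_table <- function(state, lookup) {
  require_editor(state)
  stopifnot(inherits(lookup, "edc_lookup"))
  if (!is.null(find_lookup(state$metadata, lookup$lookup_table_id))) {
    edc_error("DUPLICATE_LOOKUP_ID",
              sprintf("lookup table '%s' already exists", lookup$lookup_table_id))
  }
  state$metadata$lookup_tables <- c(state$metadata$lookup_tables, list(lookup))
  bump_metadata_version(state)
  invisible(state)
}

# ---- lifecycle transitions --------------------------------------------------

#' Activate deployment mode
#'
#' Requires editor mode and metadata that passes [validate_study_metadata()]
#' with no findings. The transient preview store is purged (test entries are
#' never carried over), the current visit and widget definitions become
#' frozen, and permanent data capture opens.
#'
#' @param state an `edc_study_state`.
#' @param actor acting user token.
#' @return the state, invisibly.
#' @export
activate_deployment <- function(state, actor) {
  if (state$mode == "deployment") {
    edc_error("ALREADY_DEPLOYED", "the study is already in deployment mode")
  }
  rep <- validate_study_metadata(state$metadata)
  if (!report_ok(rep)) {
    edc_error("INVALID_METADATA",
              "metadata must pass validation before deployment",
              data = list(report = rep))
  }
  state$preview_store <- audit_store(origin_id = state$origin_id,
                                     clock = state$clock,
                                     study_id = state$study_id)
  state$mode <- "deployment"
  state$deployed_at <- state$clock()
  state$frozen_visits <- union(state$frozen_visits,
                               visit_ids_of(state$metadata))
  state$frozen_widgets <- union(state$frozen_widgets,
                                widget_ids(state$metadata))
  state$store$metadata_version <- state$metadata$metadata_version
  log_state_event(state, "DEPLOYED",
                  sprintf("deployment activated by %s", actor))
  invisible(state)
}

#' Revert a deployed study to editor mode
#'
#' Administrator-only. Deployed clinical data remains untouched in the
#' audit store; a warning event is logged. Visits deployed earlier stay
#' frozen — only additive metadata changes are accepted until the next
#' activation.
#'
#' @param state an `edc_study_state`.
#' @param actor acting user token.
#' @param role `"admin"` or `"user"`; roles are supplied by the caller
#'   (authentication is the deployment stack's concern).
#' @return the state, invisibly.
#' @export
revert_to_editor <- function(state, actor, role = "user") {
  if (state$mode != "deployment") {
    edc_error("NOT_DEPLOYED", "the study is not in deployment mode")
  }
  if (!identical(role, "admin")) {
    edc_error("NOT_ADMIN", "only an administrator may revert to editor mode")
  }
  state$mode <- "editor"
  log_state_event(state, "REVERTED_TO_EDITOR",
                  sprintf("warning: study reverted to editor mode by %s", actor))
  invisible(state)
}

# ---- participants -----------------------------------------------------------

#' Include (pseudonymize) a participant
#'
#' Assigns the next pseudonymized ID for the site — scheme
#' `{site}-{seq:04d}` — and persists the registration through the audit
#' store. Only possible in deployment mode.
#'
#' @param state an `edc_study_state` in deployment mode.
#' @param site site token (lowercase snake case).
#' @param actor acting user token.
#' @return an `edc_participant`: list with `pid`, `site`, `included_at`,
#'   `record_id`.
#' @export
include_participant <- function(state, site, actor) {
  if (state$mode != "deployment") {
    edc_error("NOT_DEPLOYED", "participants can only be included in deployment mode")
  }
  if (!is_token(site)) {
    edc_error("BAD_SITE", sprintf("'%s' is not a valid site token", site))
  }
  seq_no <- (state$site_seq[[site]] %||% 0L) + 1L
  pid <- sprintf("%s-%04d", site, seq_no)
  record_id <- uuid4()
  row <- append_version(state$store, record_id,
                        payload = list(pid = pid, site = site),
                        actor = actor, entity = "participant")
  # the row timestamp is the authoritative inclusion time
  state$site_seq[[site]] <- seq_no
  state$participants[[pid]] <- record_id
  structure(list(pid = pid, site = site, included_at = row$timestamp,
                 record_id = record_id),
            class = "edc_participant")
}

#' Does a pseudonymized participant ID exist?
#'
#' The complete server-side contract the mobile client needs before serving
#' a form: `TRUE` iff the PID belongs to a currently included (non-deleted)
#' participant.
#'
#' @param state an `edc_study_state`.
#' @param pid participant id.
#' @return logical.
#' @export
pid_exists <- function(state, pid) {
  record_id <- state$participants[[pid]]
  if (is.null(record_id)) return(FALSE)
  head <- record_head(state$store, record_id)
  !is.null(head) && !head$deleted
}

# ---- data entry -------------------------------------------------------------

entry_key <- function(pid, visit_id, visit_instance) {
  paste(pid, visit_id, visit_instance, sep = "\x1f")
}

current_entry_row <- function(state, pid, visit_id, visit_instance,
                              store = active_store(state)) {
  rid <- state$entry_index[[entry_key(pid, visit_id, visit_instance)]]
  if (is.null(rid)) return(NULL)
  head <- record_head(store, rid)
  if (is.null(head) || head$deleted) NULL else head
}

# typed current values for one (pid, visit, instance), including the
# participant-centered values, as consumed by build_form_spec
entry_values <- function(state, pid, visit_id, visit_instance) {
  vals <- list()
  pc <- current_entry_row(state, pid, PARTICIPANT_VISIT, 1L)
  rows <- list(pc)
  if (!identical(visit_id, PARTICIPANT_VISIT)) {
    rows <- c(rows, list(current_entry_row(state, pid, visit_id, visit_instance)))
  }
  wenv <- widget_env(state$metadata)
  lenv <- lookup_env(state$metadata)
  for (row in rows) {
    if (is.null(row)) next
    for (k in names(row$payload$values)) {
      w <- wenv[[k]]
      if (is.null(w)) next
      lk <- if (!is.null(w$lookup_table_id)) lenv[[w$lookup_table_id]]
      v <- coerce_value(row$payload$values[[k]], w, lk)
      if (!is_coercion_failure(v) && !value_missing(v)) vals[[k]] <- v
    }
  }
  vals
}

#' Submit an entry form for a participant visit
#'
#' Builds the form for the participant's current values, validates the raw
#' submission ([validate_submission()]), strips values for hidden widgets,
#' and persists the canonical value set through [append_version()] in the
#' active store (the permanent store in deployment mode, the transient
#' preview store in editor mode). A complete submission must validate
#' cleanly or `SUBMISSION_INVALID` is raised with the report attached.
#'
#' @param state an `edc_study_state`.
#' @param pid participant id (must be included when in deployment mode).
#' @param visit_id visit id or [PARTICIPANT_VISIT].
#' @param values named character values (variable id -> raw string).
#' @param actor acting user token.
#' @param visit_instance instance number for repeating visits.
#' @param complete completeness assertion; `FALSE` allows partial saves.
#' @return the validation report, invisibly.
#' @export
submit_entry <- function(state, pid, visit_id, values, actor,
                         visit_instance = 1L, complete = TRUE) {
  if (!identical(visit_id, PARTICIPANT_VISIT)) {
    v <- find_visit(state$metadata, visit_id)
    if (is.null(v)) {
      edc_error("UNKNOWN_VISIT", sprintf("visit '%s' is not defined", visit_id))
    }
    if (visit_instance > 1L && !v$repeating) {
      edc_error("NOT_REPEATING",
                sprintf("visit '%s' does not repeat", visit_id))
    }
  }
  if (state$mode == "deployment" && !pid_exists(state, pid)) {
    edc_error("UNKNOWN_PARTICIPANT", sprintf("no participant '%s'", pid))
  }

  current <- entry_values(state, pid, visit_id, visit_instance)
  form <- build_form_spec(state$metadata, visit_id, current,
                          participant_id = pid,
                          visit_instance = as.integer(visit_instance))
  sub <- submission(pid, visit_id, values, actor,
                    visit_instance = as.integer(visit_instance),
                    complete = complete)
  report <- validate_submission(state$metadata, form, sub)
  if (!report_ok(report)) {
    edc_error("SUBMISSION_INVALID", "submission fails validation",
              data = list(report = report))
  }

  # effective values: submitted keys override stored ones; then coerce,
  # re-evaluate visibility and strip hidden values before storage
  stored <- list()
  prev <- current_entry_row(state, pid, visit_id, visit_instance)
  if (!is.null(prev)) stored <- prev$payload$values
  raw_effective <- stored
  for (k in names(sub$values)) raw_effective[[k]] <- sub$values[[k]]

  widgets <- widgets_for_visit(state$metadata, visit_id)
  typed <- list()
  for (w in widgets) {
    k <- w$variable_id
    if (is.null(raw_effective[[k]])) next
    lk <- if (!is.null(w$lookup_table_id))
      find_lookup(state$metadata, w$lookup_table_id)
    v <- coerce_value(raw_effective[[k]], w, lk)
    if (!is_coercion_failure(v) && !value_missing(v)) typed[[k]] <- v
  }
  # visibility against the union with participant-centered values
  ctx <- typed
  if (!identical(visit_id, PARTICIPANT_VISIT)) {
    pcvals <- entry_values(state, pid, PARTICIPANT_VISIT, 1L)
    for (k in setdiff(names(pcvals), names(ctx))) ctx[[k]] <- pcvals[[k]]
  }
  final <- list()
  for (w in widgets) {
    k <- w$variable_id
    if (is.null(typed[[k]])) next
    if (!evaluate_condition(w$condition, ctx)) next  # stripped hidden value
    final[[k]] <- render_value(typed[[k]], w)
  }

  key <- entry_key(pid, visit_id, visit_instance)
  rid <- state$entry_index[[key]]
  if (is.null(rid)) {
    rid <- uuid4()
    state$entry_index[[key]] <- rid
  }
  payload <- list(pid = pid, visit_id = visit_id,
                  visit_instance = as.integer(visit_instance),
                  complete = isTRUE(complete), values = final)
  append_version(active_store(state), rid, payload, actor,
                 entity = "visit_data")
  invisible(report)
}

# ---- documentation status ---------------------------------------------------

#' Documentation status of one participant
#'
#' Per (visit, instance): `empty` when no values are stored, `complete` when
#' the last submission asserted completeness (and therefore validated
#' cleanly when it was persisted), else `partial`.
#'
#' @param state an `edc_study_state`.
#' @param pid participant id.
#' @return a data frame (`visit_id`, `visit_instance`, `status`) of class
#'   `edc_documentation_status`, ordered by visit order; includes a
#'   [PARTICIPANT_VISIT] row when participant-centered widgets exist.
#' @export
documentation_status <- function(state, pid) {
  if (state$mode == "deployment" && !pid_exists(state, pid)) {
    edc_error("UNKNOWN_PARTICIPANT", sprintf("no participant '%s'", pid))
  }
  visits <- state$metadata$visits
  visits <- visits[order(vapply(visits, function(v) v$order_index, integer(1)))]
  out <- list()
  add_row <- function(visit_id, instance) {
    row <- current_entry_row(state, pid, visit_id, instance)
    status <- if (is.null(row) || length(row$payload$values) == 0) "empty"
      else if (isTRUE(row$payload$complete)) "complete"
      else "partial"
    out[[length(out) + 1L]] <<- data.frame(
      visit_id = visit_id, visit_instance = as.integer(instance),
      status = status, stringsAsFactors = FALSE)
  }
  for (v in visits) {
    instances <- 1L
    if (v$repeating) {
      k <- 1L
      while (!is.null(state$entry_index[[entry_key(pid, v$visit_id, k + 1L)]])) {
        k <- k + 1L
      }
      instances <- seq_len(k)
    }
    for (i in instances) add_row(v$visit_id, i)
  }
  if (length(widgets_for_visit(state$metadata, PARTICIPANT_VISIT)) > 0) {
    add_row(PARTICIPANT_VISIT, 1L)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("edc_documentation_status", "data.frame")
  df
}
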