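#' Coercion and rendering of raw input values
#'
#' Raw submissions arrive as flat key-to-string records. [coerce_value()]
#' turns one raw string into the widget's typed value; [render_value()] is
#' its inverse, producing the canonical string stored and exported:
#'
#' * `text` — trimmed unicode string
#' * `integer` — base-10 integer, optional sign, no grouping
#' * `float` — decimal number with `.` separator
#' * `checkbox` — boolean from `true`/`false`/`1`/`0` (case-insensitive),
#'   rendered `true`/`false`
#' * `date` — ISO 8601 calendar date (`YYYY-MM-DD`, validated)
#' * `time` — 24-hour `HH:MM`
#' * `radio`/`dropdown` — one of the widget's choice codes
#' * `dropdown_search` — one of the referenced lookup table's codes
#'
#' The empty string coerces to the explicit missing value `NA`. Failures are
#' returned as coercion-failure objects (never raised); they surface as
#' `COERCION_ERROR` entries in validation reports.
#'
#' @param raw a single raw input string (or `NA`).
#' @param widget the `edc_widget` defining the expected type.
#' @param lookup for `dropdown_search`, the `edc_lookup` with the valid
#'   codes; omit to skip code-membership checking.
#' @return the typed value, `NA` for missing, or an `edc_coercion_failure`.
#' @export
coerce_value <- function(raw, widget, lookup = NULL) {
  fail <- function() {
    structure(list(code = "COERCION_ERROR", variable_id = widget$variable_id,
                   expected = widget$input_type, raw = raw),
              class = "edc_coercion_failure")
  }
  if (is.null(raw) || length(raw) != 1 || is.na(raw)) return(NA)
  raw <- trimws(as.character(raw))
  if (!nzchar(raw)) return(NA)
  switch(widget$input_type,
    text = raw,
    integer = {
      if (!grepl("^[+-]?[0-9]+$", raw)) return(fail())
      v <- suppressWarnings(as.integer(raw))
      if (is.na(v)) return(fail())  # out of integer range
      v
    },
    float = {
      if (!grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", raw)) {
        return(fail())
      }
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) return(fail())
      v
    },
    checkbox = {
      v <- as_flag(raw)
      if (is.na(v)) return(fail())
      v
    },
    date = {
      if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", raw)) return(fail())
      d <- as.Date(raw, format = "%Y-%m-%d")
      # reject impossible calendar dates such as 2021-02-30
      if (is.na(d) || format(d, "%Y-%m-%d") != raw) return(fail())
      raw
    },
    time = {
      if (!grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", raw)) return(fail())
      raw
    },
    radio = ,
    dropdown = {
      if (is.null(widget$choices) || !raw %in% widget$choices$code) {
        return(fail())
      }
      raw
    },
    dropdown_search = {
      if (!is.null(lookup) && !raw %in% lookup$entries$code) return(fail())
      if (is.null(lookup) && !is_code(raw)) return(fail())
      raw
    },
    fail()
  )
}

#' @rdname coerce_value
#' @param value a typed value as returned by [coerce_value()].
#' @return the canonical string form; missing values render as `""`.
#' @export
render_value <- function(value, widget) {
  if (is.null(value) || length(value) != 1 || is.na(value)) return("")
  switch(widget$input_type,
    integer = sprintf("%d", as.integer(value)),
    float = format(as.numeric(value), scientific = FALSE, trim = TRUE,
                   digits = 15),
    checkbox = if (isTRUE(as_flag(value))) "true" else "false",
    as.character(value)
  )
}

#' Is a value a coercion failure?
#' @param x any object.
#' @export
is_coercion_failure <- function(x) inherits(x, "edc_coercion_failure")

# ---- form specification -----------------------------------------------------

#' Reserved visit id addressing the participant-centered form
#'
#' Widgets with an empty `visit_ids` are captured independently of study
#' visits (e.g. diagnoses or medications); their form is requested under
#' this pseudo visit id.
#' @export
PARTICIPANT_VISIT <- "participant"

widgets_for_visit <- function(study, visit_id) {
  sel <- if (identical(visit_id, PARTICIPANT_VISIT)) {
    Filter(function(w) length(w$visit_ids) == 0, study$widgets)
  } else {
    Filter(function(w) visit_id %in% w$visit_ids, study$widgets)
  }
  if (length(sel) == 0) return(sel)
  sel[order(vapply(sel, function(w) w$order_index, integer(1)))]
}

#' Build the abstract form for one visit of one participant
#'
#' Renders the form specification the user interface (or a headless caller)
#' needs: the visit's widgets in `order_index` order, each with its current
#' value and a visibility flag computed from its display condition against
#' the supplied values. Hidden widgets stay listed with `visible = FALSE`;
#' the renderer decides how to display them.
#'
#' @param study an `edc_study_metadata`.
#' @param visit_id a defined visit id, or [PARTICIPANT_VISIT] for the
#'   participant-centered form.
#' @param values named list of current typed values — the union of this
#'   visit instance's values and the participant-centered values.
#' @param participant_id optional participant id carried in the spec.
#' @param visit_instance instance number (>= 1) for repeating visits.
#' @return an object of class `edc_form_spec`.
#' @export
build_form_spec <- function(study, visit_id, values = list(),
                            participant_id = NULL, visit_instance = 1L) {
  if (!identical(visit_id, PARTICIPANT_VISIT) &&
      is.null(find_visit(study, visit_id))) {
    edc_error("UNKNOWN_VISIT", sprintf("visit '%s' is not defined", visit_id))
  }
  items <- lapply(widgets_for_visit(study, visit_id), function(w) {
    list(widget = w,
         value = if (is.null(values[[w$variable_id]])) NA else values[[w$variable_id]],
         visible = evaluate_condition(w$condition, values))
  })
  structure(list(study_id = study$study_id, visit_id = visit_id,
                 participant_id = participant_id,
                 visit_instance = as.integer(visit_instance),
                 items = items),
            class = "edc_form_spec")
}

#' @export
print.edc_form_spec <- function(x, ...) {
  vis <- sum(vapply(x$items, function(it) it$visible, logical(1)))
  cat(sprintf("<form %s/%s instance %d: %d widgets (%d visible)>\n",
              x$study_id, x$visit_id, x$visit_instance, length(x$items), vis))
  invisible(x)
}

form_widget_ids <- function(form) {
  vapply(form$items, function(it) it$widget$variable_id, character(1))
}

#' Construct a submission
#'
#' A submission is one flat key-to-raw-string record for one participant,
#' visit and visit instance. `complete` asserts that the user considers the
#' form finished; only then are required-field checks enforced.
#'
#' @param participant_id participant id (PID).
#' @param visit_id visit id or [PARTICIPANT_VISIT].
#' @param values named character vector or list mapping variable ids to raw
#'   input strings.
#' @param submitted_by actor token.
#' @param visit_instance instance number (>= 1).
#' @param complete logical completeness assertion.
#' @return an object of class `edc_submission`.
#' @export
submission <- function(participant_id, visit_id, values, submitted_by,
                       visit_instance = 1L, complete = TRUE) {
  values <- as.list(values)
  stopifnot(length(values) == 0 || !is.null(names(values)))
  values <- lapply(values, function(v) as.character(v)[1])
  structure(list(participant_id = as.character(participant_id),
                 visit_id = as.character(visit_id),
                 visit_instance = as.integer(visit_instance),
                 values = values,
                 submitted_by = as.character(submitted_by),
                 complete_flag = isTRUE(complete)),
            class = "edc_submission")
}

#' Validate a submission against its form
#'
#' Checks a raw submission against the form built for the same participant,
#' visit and instance. The report contains:
#'
#' * `UNKNOWN_VARIABLE` (error) — keys outside the form;
#' * `COERCION_ERROR` (error) — values that do not parse as the widget's type;
#' * `MISSING_REQUIRED` (error, only when `complete_flag` is set) — visible
#'   required widgets left empty;
#' * `VALUE_FOR_HIDDEN` (warning) — values supplied to widgets hidden by
#'   skip logic; these are stripped before storage.
#'
#' Visibility is re-evaluated against the effective values (submitted values
#' where supplied, the form's current values otherwise), so toggling a
#' controlling answer within the same submission is honored. A complete
#' submission must validate with `report_ok() == TRUE` before it is
#' persisted; with `complete_flag = FALSE` only type checks apply (partial
#' saves never store uncoercible data).
#'
#' @param study an `edc_study_metadata`.
#' @param form the `edc_form_spec` the submission answers.
#' @param sub an `edc_submission`.
#' @return an `edc_validation_report`.
#' @export
validate_submission <- function(study, form, sub) {
  entries <- list()
  add <- function(variable_id, code, msg, severity = "error") {
    entries[[length(entries) + 1L]] <<-
      new_report_entry(variable_id, code, msg, severity)
  }
  if (!identical(form$visit_id, sub$visit_id) ||
      !identical(form$visit_instance, sub$visit_instance) ||
      (!is.null(form$participant_id) &&
       !identical(form$participant_id, sub$participant_id))) {
    add(NULL, "FORM_MISMATCH",
        "submission does not address the form's participant/visit/instance")
    return(validation_report(entries))
  }

  fids <- form_widget_ids(form)
  unknown <- setdiff(names(sub$values), fids)
  for (k in unknown) {
    add(k, "UNKNOWN_VARIABLE", sprintf("'%s' is not part of this form", k))
  }

  # coerce submitted values; build the effective typed value map
  effective <- list()
  for (it in form$items) {
    if (!value_missing(it$value)) effective[[it$widget$variable_id]] <- it$value
  }
  wenv <- widget_env(study)
  lenv <- lookup_env(study)
  coerced <- list()
  for (k in intersect(names(sub$values), fids)) {
    w <- wenv[[k]]
    lk <- if (!is.null(w$lookup_table_id)) lenv[[w$lookup_table_id]]
    v <- coerce_value(sub$values[[k]], w, lk)
    if (is_coercion_failure(v)) {
      add(k, "COERCION_ERROR",
          sprintf("'%s' is not a valid %s value", sub$values[[k]], w$input_type))
    } else {
      coerced[[k]] <- v
      if (value_missing(v)) effective[k] <- list(NULL) else effective[[k]] <- v
    }
  }

  # visibility on the effective values
  visible <- logical(0)
  for (it in form$items) {
    visible[it$widget$variable_id] <-
      evaluate_condition(it$widget$condition, effective)
  }

  for (k in names(coerced)) {
    if (!visible[[k]] && !value_missing(coerced[[k]])) {
      add(k, "VALUE_FOR_HIDDEN",
          sprintf("'%s' is hidden by its display condition; value will be stripped", k),
          severity = "warning")
    }
  }

  if (sub$complete_flag) {
    for (it in form$items) {
      wid <- it$widget$variable_id
      if (!it$widget$required || !visible[[wid]]) next
      v <- if (wid %in% names(coerced)) coerced[[wid]] else effective[[wid]]
      if (value_missing(v)) {
        add(wid, "MISSING_REQUIRED",
            sprintf("required field '%s' is empty", wid))
      }
    }
  }

  validation_report(entries)
}
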