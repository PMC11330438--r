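#' Supported input widget types
#'
#' The nine input types an eCRF widget can take: free text, integers, floats,
#' checkboxes, time of day, calendar date, radio buttons, drop-down choice
#' menus, and searchable drop-downs backed by a controlled-vocabulary lookup
#' table (for large dictionaries such as ICD-10 or ICHI).
#'
#' @export
INPUT_TYPES <- c("text", "integer", "float", "checkbox", "time", "date",
                 "radio", "dropdown", "dropdown_search")

CHOICE_TYPES <- c("radio", "dropdown")

as_choices <- function(choices) {
  if (is.null(choices)) return(NULL)
  if (is.data.frame(choices)) {
    stopifnot(all(c("code", "label") %in% names(choices)))
    df <- data.frame(code = as.character(choices$code),
                     label = as.character(choices$label),
                     stringsAsFactors = FALSE)
  } else {
    # list of c(code, label) pairs
    df <- data.frame(code = vapply(choices, function(p) as.character(p[[1]]), character(1)),
                     label = vapply(choices, function(p) as.character(p[[2]]), character(1)),
                     stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Define an input widget
#'
#' A widget is the complete metadata of one study variable: what input is
#' rendered, how it is labeled, in which visits it appears, whether it is
#' required, and under which condition it is shown. A widget with an empty
#' `visit_ids` is participant-centered: its data (e.g. diagnoses,
#' medications) is captured independently of study visits.
#'
#' @param variable_id unique identifier, lowercase snake case (`[a-z][a-z0-9_]*`,
#'   at most 64 characters).
#' @param input_type one of [INPUT_TYPES].
#' @param label human-readable field label.
#' @param required must the field be filled before a form counts as complete?
#' @param visit_ids character vector of visit ids; empty for
#'   participant-centered widgets.
#' @param choices for `radio`/`dropdown`: a data frame with columns
#'   `code`,`label`, or a list of `c(code, label)` pairs.
#' @param lookup_table_id for `dropdown_search`: id of the lookup table
#'   holding the vocabulary.
#' @param condition display condition: an `edc_condition` or its canonical
#'   string form (see [conditions]).
#' @param order_index non-negative integer ordering the widget within forms.
#' @param units optional measurement units shown with the field.
#' @param help_text optional guidance text.
#' @return an object of class `edc_widget`.
#' @export
widget_definition <- function(variable_id, input_type, label,
                              required = FALSE, visit_ids = character(0),
                              choices = NULL, lookup_table_id = NULL,
                              condition = NULL, order_index = 0L,
                              units = NULL, help_text = NULL) {
  if (is.character(condition)) condition <- parse_condition(condition)
  structure(list(
    variable_id = as.character(variable_id),
    input_type = as.character(input_type),
    label = as.character(label),
    required = isTRUE(required),
    visit_ids = as.character(visit_ids),
    choices = as_choices(choices),
    lookup_table_id = blank_to_null(lookup_table_id),
    condition = condition,
    order_index = as.integer(order_index),
    units = blank_to_null(units),
    help_text = blank_to_null(help_text)
  ), class = "edc_widget")
}

#' @export
print.edc_widget <- function(x, ...) {
  cat(sprintf("<widget %s: %s%s, \"%s\">\n", x$variable_id, x$input_type,
              if (x$required) ", required" else "", x$label))
  invisible(x)
}

#' Define a study visit
#'
#' @param visit_id unique visit identifier (lowercase snake case).
#' @param title human-readable visit title.
#' @param order_index non-negative integer; unique among the study's visits.
#' @param repeating may a participant have more than one instance of this
#'   visit (e.g. one per treatment intervention)?
#' @param mobile is the visit's form also served to the mobile client?
#' @return an object of class `edc_visit`.
#' @export
visit_definition <- function(visit_id, title = visit_id, order_index = 0L,
                             repeating = FALSE, mobile = FALSE) {
  structure(list(visit_id = as.character(visit_id),
                 title = as.character(title),
                 order_index = as.integer(order_index),
                 repeating = isTRUE(repeating),
                 mobile = isTRUE(mobile)),
            class = "edc_visit")
}

#' Define a controlled-vocabulary lookup table
#'
#' Lookup tables back `dropdown_search` widgets; dictionaries such as ICD-10,
#' ICHI or SNOMED subsets are uploaded as `code,label` tables.
#'
#' @param lookup_table_id unique identifier (lowercase snake case).
#' @param name human-readable name.
#' @param entries data frame with columns `code`,`label` (at least one row,
#'   unique codes), or a list of `c(code, label)` pairs.
#' @return an object of class `edc_lookup`.
#' @export
lookup_table <- function(lookup_table_id, name, entries) {
  structure(list(lookup_table_id = as.character(lookup_table_id),
                 name = as.character(name),
                 entries = as_choices(entries)),
            class = "edc_lookup")
}

#' Bundle widgets as a reusable variable set
#'
#' Variable sets are the unit of the widget library: a published set of
#' widget definitions (with any lookup tables they reference) that can be
#' imported into a visit of another study via [import_variable_set()].
#' Visit assignments are cleared on construction; the set binds to a visit
#' only at import time.
#'
#' @param name human-readable set name.
#' @param widgets list of `edc_widget`.
#' @param lookup_tables list of `edc_lookup` referenced by the widgets.
#' @return an object of class `edc_variable_set`.
#' @export
variable_set <- function(name, widgets, lookup_tables = list()) {
  widgets <- lapply(widgets, function(w) { w$visit_ids <- character(0); w })
  structure(list(name = as.character(name), widgets = widgets,
                 lookup_tables = lookup_tables),
            class = "edc_variable_set")
}

#' Assemble study metadata
#'
#' The complete metadata of one study: visits, widgets and lookup tables,
#' plus a monotone `metadata_version` that is bumped on every editor-mode
#' save. All engine behavior — form rendering, validation, export, the
#' codebook — is driven by this object.
#'
#' @param study_id study identifier (lowercase snake case).
#' @param title study title.
#' @param visits list of `edc_visit`.
#' @param widgets list of `edc_widget`.
#' @param lookup_tables list of `edc_lookup`.
#' @param metadata_version integer >= 1.
#' @return an object of class `edc_study_metadata`.
#' @export
study_metadata <- function(study_id, title = study_id, visits = list(),
                           widgets = list(), lookup_tables = list(),
                           metadata_version = 1L) {
  structure(list(study_id = as.character(study_id),
                 title = as.character(title),
                 visits = visits,
                 widgets = widgets,
                 lookup_tables = lookup_tables,
                 metadata_version = as.integer(metadata_version)),
            class = "edc_study_metadata")
}

#' @export
print.edc_study_metadata <- function(x, ...) {
  cat(sprintf("<study %s v%d: %d visit%s, %d widget%s, %d lookup table%s>\n",
              x$study_id, x$metadata_version,
              length(x$visits), if (length(x$visits) == 1) "" else "s",
              length(x$widgets), if (length(x$widgets) == 1) "" else "s",
              length(x$lookup_tables),
              if (length(x$lookup_tables) == 1) "" else "s"))
  invisible(x)
}

# ---- lookups into metadata --------------------------------------------------

#' Accessors over study metadata
#'
#' `widget_ids()` returns the variable ids of all widgets in definition
#' order; `study_visit_ids()` the visit ids in definition order.
#'
#' @param study an `edc_study_metadata`.
#' @return a character vector.
#' @export
widget_ids <- function(study) {
  vapply(study$widgets, function(w) w$variable_id, character(1))
}

#' @rdname widget_ids
#' @export
study_visit_ids <- function(study) visit_ids_of(study)

visit_ids_of <- function(study) {
  vapply(study$visits, function(v) v$visit_id, character(1))
}

lookup_ids_of <- function(study) {
  vapply(study$lookup_tables, function(l) l$lookup_table_id, character(1))
}

find_widget <- function(study, variable_id) {
  for (w in study$widgets) if (w$variable_id == variable_id) return(w)
  NULL
}

# hashed widget/lookup maps for hot paths (per-call construction is O(n),
# lookups O(1); the metadata list itself stays the source of truth)
widget_env <- function(study) {
  e <- new.env(parent = emptyenv(), size = max(29L, length(study$widgets)))
  for (w in study$widgets) assign(w$variable_id, w, envir = e)
  e
}

lookup_env <- function(study) {
  e <- new.env(parent = emptyenv())
  for (l in study$lookup_tables) assign(l$lookup_table_id, l, envir = e)
  e
}

find_visit <- function(study, visit_id) {
  for (v in study$visits) if (v$visit_id == visit_id) return(v)
  NULL
}

find_lookup <- function(study, lookup_table_id) {
  for (l in study$lookup_tables) {
    if (l$lookup_table_id == lookup_table_id) return(l)
  }
  NULL
}

# ---- widget validation ------------------------------------------------------

ORDERED_TYPES <- c("integer", "float", "date", "time")
SET_TYPES <- c("text", "radio", "dropdown", "dropdown_search")

# literal-type compatibility of one condition atom against the referenced
# widget; returns NULL when compatible, else a message.
atom_type_problem <- function(atom, ref_widget) {
  ty <- ref_widget$input_type
  op <- atom$op
  lit <- atom$literal
  if (op %in% c("is_empty", "not_empty")) return(NULL)
  if (op %in% c("lt", "le", "gt", "ge") && !ty %in% ORDERED_TYPES) {
    return(sprintf("ordered comparison not defined for %s widget '%s'",
                   ty, ref_widget$variable_id))
  }
  if (op == "in_set") {
    if (!ty %in% SET_TYPES) {
      return(sprintf("in_set not defined for %s widget '%s'", ty,
                     ref_widget$variable_id))
    }
    if (ty %in% CHOICE_TYPES && !all(lit %in% ref_widget$choices$code)) {
      return(sprintf("codes %s are not choices of '%s'",
                     paste(setdiff(lit, ref_widget$choices$code), collapse = ","),
                     ref_widget$variable_id))
    }
    return(NULL)
  }
  expected <- switch(ty,
    integer = , float = "numeric",
    checkbox = "logical",
    "character")
  actual <- if (is.numeric(lit)) "numeric" else if (is.logical(lit)) "logical" else "character"
  if (expected != actual) {
    return(sprintf("literal %s is %s but widget '%s' is %s",
                   quote_literal(lit), actual, ref_widget$variable_id, ty))
  }
  if (ty %in% c("date", "time") && is.character(lit)) {
    probe <- coerce_value(lit, ref_widget)
    if (is_coercion_failure(probe)) {
      return(sprintf("literal %s is not a valid %s", quote_literal(lit), ty))
    }
  }
  if (ty %in% CHOICE_TYPES && !lit %in% ref_widget$choices$code) {
    return(sprintf("code %s is not a choice of '%s'", quote_literal(lit),
                   ref_widget$variable_id))
  }
  NULL
}

validate_widget_core <- function(widget, study, check_duplicate = TRUE) {
  entries <- list()
  add <- function(code, msg, severity = "error") {
    entries[[length(entries) + 1L]] <<-
      new_report_entry(widget$variable_id, code, msg, severity)
  }

  if (!is_token(widget$variable_id)) {
    add("BAD_VARIABLE_ID",
        sprintf("'%s' is not a valid identifier (lowercase snake case, <= 64 chars)",
                widget$variable_id))
  }
  if (!widget$input_type %in% INPUT_TYPES) {
    add("UNKNOWN_INPUT_TYPE",
        sprintf("input type '%s' is not one of: %s", widget$input_type,
                paste(INPUT_TYPES, collapse = ", ")))
    return(validation_report(entries))  # nothing further can be checked
  }
  if (is.na(widget$order_index) || widget$order_index < 0) {
    add("BAD_ORDER_INDEX", "order_index must be a non-negative integer")
  }

  if (check_duplicate) {
    clash <- Filter(function(w) w$variable_id == widget$variable_id &&
                      !identical(w, widget), study$widgets)
    if (length(clash) > 0) {
      add("DUPLICATE_ID",
          sprintf("variable_id '%s' is already defined in the study",
                  widget$variable_id))
    }
  }

  known_visits <- visit_ids_of(study)
  for (vid in widget$visit_ids) {
    if (!vid %in% known_visits) {
      add("UNKNOWN_VISIT", sprintf("visit '%s' is not defined", vid))
    }
  }

  if (widget$input_type %in% CHOICE_TYPES) {
    ch <- widget$choices
    if (is.null(ch) || nrow(ch) < 2) {
      add("MISSING_CHOICES",
          sprintf("%s widgets need at least 2 choices", widget$input_type))
    } else {
      if (anyDuplicated(ch$code)) {
        add("DUPLICATE_CHOICE_CODE",
            sprintf("duplicated choice codes: %s",
                    paste(unique(ch$code[duplicated(ch$code)]), collapse = ",")))
      }
      bad <- ch$code[!vapply(ch$code, is_code, logical(1))]
      if (length(bad) > 0) {
        add("BAD_CHOICE_CODE",
            sprintf("invalid choice codes: %s", paste(bad, collapse = ",")))
      }
    }
  } else if (!is.null(widget$choices)) {
    add("CHOICES_NOT_ALLOWED",
        sprintf("%s widgets take no choice list", widget$input_type))
  }

  if (widget$input_type == "dropdown_search") {
    if (is.null(widget$lookup_table_id)) {
      add("BAD_LOOKUP_REF", "dropdown_search widgets need a lookup_table_id")
    } else if (is.null(find_lookup(study, widget$lookup_table_id))) {
      add("BAD_LOOKUP_REF",
          sprintf("lookup table '%s' is not defined", widget$lookup_table_id))
    }
  } else if (!is.null(widget$lookup_table_id)) {
    add("LOOKUP_NOT_ALLOWED",
        sprintf("%s widgets take no lookup table", widget$input_type))
  }

  if (!is.null(widget$condition)) {
    for (ref in condition_vars(widget$condition)) {
      refw <- find_widget(study, ref)
      if (is.null(refw)) {
        add("CONDITION_UNKNOWN_VAR",
            sprintf("condition references undefined variable '%s'", ref))
      }
    }
    # type-check every atom whose referenced widget exists
    check_atoms <- function(expr) {
      if (expr$kind == "atom") {
        refw <- find_widget(study, expr$variable_id)
        if (!is.null(refw)) {
          prob <- atom_type_problem(expr, refw)
          if (!is.null(prob)) add("CONDITION_TYPE_MISMATCH", prob)
        }
      } else {
        for (ch in expr$children) check_atoms(ch)
      }
    }
    check_atoms(widget$condition)
  }

  validation_report(entries)
}

#' Validate one widget definition against (possibly partial) study metadata
#'
#' All problems are reported as entries with machine-readable codes
#' (`DUPLICATE_ID`, `MISSING_CHOICES`, `BAD_LOOKUP_REF`,
#' `CONDITION_UNKNOWN_VAR`, `CONDITION_TYPE_MISMATCH`, ...); nothing is
#' raised. An empty report means the widget is admissible.
#'
#' @param widget an `edc_widget`; it need not be registered in `study` yet.
#' @param study the `edc_study_metadata` it is validated against.
#' @return an `edc_validation_report`.
#' @export
validate_widget_definition <- function(widget, study) {
  validate_widget_core(widget, study, check_duplicate = TRUE)
}

# ---- study validation -------------------------------------------------------

# DFS cycle detection over the condition-dependency graph (widget -> the
# widgets its display condition references).
condition_cycles <- function(study) {
  ids <- widget_ids(study)
  deps <- lapply(study$widgets, function(w) {
    intersect(condition_vars(w$condition), ids)
  })
  names(deps) <- ids
  color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 white 1 grey 2 black
  cyclic <- character(0)
  visit_node <- function(v) {
    color[[v]] <<- 1L
    for (u in deps[[v]]) {
      if (color[[u]] == 1L) cyclic <<- unique(c(cyclic, v, u))
      else if (color[[u]] == 0L) visit_node(u)
    }
    color[[v]] <<- 2L
  }
  for (v in ids) if (color[[v]] == 0L) visit_node(v)
  cyclic
}

#' Validate complete study metadata
#'
#' Whole-study closure of the per-widget checks plus global invariants:
#' unique variable ids, unique visit ids and visit order indices, valid
#' lookup tables, and an acyclic condition-dependency graph. An empty report
#' is required before deployment activation.
#'
#' @param study an `edc_study_metadata`.
#' @return an `edc_validation_report`.
#' @export
validate_study_metadata <- function(study) {
  entries <- list()
  add <- function(variable_id, code, msg) {
    entries[[length(entries) + 1L]] <<- new_report_entry(variable_id, code, msg)
  }

  if (!is_token(study$study_id)) {
    add(NULL, "BAD_STUDY_ID", sprintf("'%s' is not a valid study id", study$study_id))
  }
  if (is.na(study$metadata_version) || study$metadata_version < 1) {
    add(NULL, "BAD_METADATA_VERSION", "metadata_version must be >= 1")
  }

  vids <- visit_ids_of(study)
  if (anyDuplicated(vids)) {
    add(NULL, "DUPLICATE_VISIT_ID",
        sprintf("duplicated visit ids: %s",
                paste(unique(vids[duplicated(vids)]), collapse = ",")))
  }
  for (v in study$visits) {
    if (!is_token(v$visit_id)) {
      add(NULL, "BAD_VISIT_ID", sprintf("'%s' is not a valid visit id", v$visit_id))
    }
    if (is.na(v$order_index) || v$order_index < 0) {
      add(NULL, "BAD_ORDER_INDEX",
          sprintf("visit '%s' has a negative order_index", v$visit_id))
    }
  }
  ord <- vapply(study$visits, function(v) v$order_index, integer(1))
  if (anyDuplicated(ord)) {
    add(NULL, "DUPLICATE_VISIT_ORDER", "visit order_index values are not unique")
  }

  lids <- lookup_ids_of(study)
  if (anyDuplicated(lids)) {
    add(NULL, "DUPLICATE_LOOKUP_ID",
        sprintf("duplicated lookup table ids: %s",
                paste(unique(lids[duplicated(lids)]), collapse = ",")))
  }
  for (l in study$lookup_tables) {
    if (!is_token(l$lookup_table_id)) {
      add(NULL, "BAD_LOOKUP_ID",
          sprintf("'%s' is not a valid lookup table id", l$lookup_table_id))
    }
    if (is.null(l$entries) || nrow(l$entries) < 1) {
      add(NULL, "EMPTY_LOOKUP",
          sprintf("lookup table '%s' has no entries", l$lookup_table_id))
    } else if (anyDuplicated(l$entries$code)) {
      add(NULL, "DUPLICATE_LOOKUP_CODE",
          sprintf("lookup table '%s' has duplicated codes", l$lookup_table_id))
    }
  }

  ids <- widget_ids(study)
  for (dup in unique(ids[duplicated(ids)])) {
    add(dup, "DUPLICATE_ID",
        sprintf("variable_id '%s' is defined more than once", dup))
  }
  for (w in study$widgets) {
    rep_w <- validate_widget_core(w, study, check_duplicate = FALSE)
    if (nrow(rep_w) > 0) entries <- c(entries, list(rep_w))
  }

  if (!anyDuplicated(ids)) {
    cyc <- condition_cycles(study)
    for (v in cyc) {
      add(v, "CONDITION_CYCLE",
          sprintf("widget '%s' is part of a condition-dependency cycle", v))
    }
  }

  validation_report(entries)
}

# ---- library import ---------------------------------------------------------

next_free_id <- function(base, taken) {
  if (!base %in% taken) return(base)
  k <- 2L
  repeat {
    cand <- paste0(base, "_", k)
    if (!cand %in% taken) return(cand)
    k <- k + 1L
  }
}

rename_condition_vars <- function(expr, mapping) {
  if (is.null(expr)) return(NULL)
  if (expr$kind == "atom") {
    if (expr$variable_id %in% names(mapping)) {
      expr$variable_id <- mapping[[expr$variable_id]]
    }
    expr
  } else {
    expr$children <- lapply(expr$children, rename_condition_vars, mapping)
    expr
  }
}

#' Import a variable set from the library into a visit
#'
#' Appends the set's widgets to `target_visit`, with order indices continuing
#' after the study's existing widgets. On a `variable_id` collision the
#' incoming id is deterministically suffixed `_2`, `_3`, ...; conditions
#' referencing renamed set-internal variables are rewritten accordingly.
#' Lookup tables travelling with the set are merged (reused when an
#' identical table already exists, suffixed when the id is taken by a
#' different table). `metadata_version` is incremented.
#'
#' @param set an `edc_variable_set`.
#' @param study an `edc_study_metadata`, or an `edc_study_state` in editor
#'   mode (deployment mode raises `STUDY_NOT_IN_EDITOR_MODE`).
#' @param target_visit id of the visit receiving the widgets.
#' @return a new `edc_study_metadata` (or the updated state when a state was
#'   given).
#' @export
import_variable_set <- function(set, study, target_visit) {
  if (inherits(study, "edc_study_state")) {
    state <- study
    if (state$mode != "editor") {
      edc_error("STUDY_NOT_IN_EDITOR_MODE",
                "variable sets can only be imported in editor mode")
    }
    state$metadata <- import_variable_set(set, state$metadata, target_visit)
    return(invisible(state))
  }
  stopifnot(inherits(set, "edc_variable_set"),
            inherits(study, "edc_study_metadata"))
  if (is.null(find_visit(study, target_visit))) {
    edc_error("UNKNOWN_VISIT", sprintf("visit '%s' is not defined", target_visit))
  }

  # merge lookup tables first (widgets may reference them); lut_map records
  # original id -> id under which the table lives in the host study
  lut_map <- character(0)
  for (l in set$lookup_tables) {
    orig_id <- l$lookup_table_id
    existing <- find_lookup(study, orig_id)
    if (!is.null(existing) && identical(existing$entries, l$entries)) {
      lut_map[orig_id] <- orig_id
    } else if (is.null(existing)) {
      study$lookup_tables <- c(study$lookup_tables, list(l))
      lut_map[orig_id] <- orig_id
    } else {
      new_id <- next_free_id(orig_id, lookup_ids_of(study))
      l$lookup_table_id <- new_id
      study$lookup_tables <- c(study$lookup_tables, list(l))
      lut_map[orig_id] <- new_id
    }
  }

  taken <- widget_ids(study)
  base_order <- if (length(study$widgets) > 0) {
    max(vapply(study$widgets, function(w) w$order_index, integer(1))) + 1L
  } else 0L

  id_map <- character(0)
  new_widgets <- list()
  for (i in seq_along(set$widgets)) {
    w <- set$widgets[[i]]
    new_id <- next_free_id(w$variable_id, taken)
    id_map[w$variable_id] <- new_id
    taken <- c(taken, new_id)
    w$variable_id <- new_id
    w$visit_ids <- target_visit
    w$order_index <- base_order + i - 1L
    if (!is.null(w$lookup_table_id) && w$lookup_table_id %in% names(lut_map)) {
      w$lookup_table_id <- unname(lut_map[[w$lookup_table_id]])
    }
    new_widgets[[length(new_widgets) + 1L]] <- w
  }
  # rewrite set-internal condition references to the (possibly renamed) ids
  new_widgets <- lapply(new_widgets, function(w) {
    if (!is.null(w$condition)) {
      w$condition <- rename_condition_vars(w$condition, as.list(id_map))
    }
    w
  })

  study$widgets <- c(study$widgets, new_widgets)
  study$metadata_version <- study$metadata_version + 1L
  study
}
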