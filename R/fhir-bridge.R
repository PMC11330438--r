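# Import of study metadata from FHIR R4 Questionnaire resources and of
# clinical data from QuestionnaireResponse resources (read from files or
# byte streams; server transport is the caller's concern).

fhir_parse <- function(x) {
  if (is.list(x)) return(x)
  stopifnot(is.character(x), length(x) == 1)
  src <- if (file.exists(x)) x else x
  out <- tryCatch(jsonlite::fromJSON(src, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(out)) edc_error("MALFORMED_RESOURCE", "cannot parse FHIR JSON")
  out
}

# linkIds are sanitized deterministically into the variable-id charset:
# lower-cased, runs of foreign characters collapsed to "_", prefixed "q_"
# when not starting with a letter, truncated to 64, uniquified with _2, _3...
sanitize_linkid <- function(link_id, taken = character(0)) {
  s <- tolower(as.character(link_id))
  s <- gsub("[^a-z0-9_]+", "_", s)
  s <- gsub("_+", "_", s)
  s <- sub("^_", "", s)
  s <- sub("_$", "", s)
  if (!nzchar(s) || !grepl("^[a-z]", s)) s <- paste0("q_", s)
  s <- sub("_$", "", s)
  s <- substr(s, 1, 64)
  next_free_id(s, taken)
}

fhir_answer_literal <- function(ew) {
  if (!is.null(ew$answerCoding)) return(as.character(ew$answerCoding$code))
  if (!is.null(ew$answerString)) return(as.character(ew$answerString))
  if (!is.null(ew$answerInteger)) return(as.numeric(ew$answerInteger))
  if (!is.null(ew$answerDecimal)) return(as.numeric(ew$answerDecimal))
  if (!is.null(ew$answerBoolean)) return(isTRUE(ew$answerBoolean))
  if (!is.null(ew$answerDate)) return(as.character(ew$answerDate))
  if (!is.null(ew$answerTime)) return(substr(as.character(ew$answerTime), 1, 5))
  NULL
}

FHIR_OP_MAP <- c("=" = "eq", "!=" = "ne", "<" = "lt", "<=" = "le",
                 ">" = "gt", ">=" = "ge")

#' Import a FHIR Questionnaire as a variable set
#'
#' Maps FHIR R4 Questionnaire items onto widget definitions:
#'
#' * `string`/`text` -> text, `integer` -> integer, `decimal` -> float,
#'   `boolean` -> checkbox, `date` -> date, `time` -> time;
#' * `choice` -> radio when it has at most 7 answer options, else dropdown
#'   (a UI convention, noted in the report so importers can override);
#' * `open-choice` -> searchable dropdown backed by a lookup table built
#'   from the answer options;
#' * `group` items are flattened with dotted id prefixes before
#'   sanitization; `display` items and unsupported types (`attachment`,
#'   `reference`, `quantity`, ...) are skipped with a reason;
#' * `enableWhen` clauses become display-condition atoms, combined with
#'   `ALL` (or `ANY` when `enableBehavior` is `"any"`); the `exists`
#'   operator maps to `not_empty`/`is_empty`. Clauses referencing skipped
#'   items are dropped with a warning.
#'
#' Identical resource bytes always yield the identical variable set and
#' report.
#'
#' @param x path to a Questionnaire JSON file, a JSON string, or a parsed
#'   list.
#' @return list with `set` (an `edc_variable_set`) and `report` (an
#'   `edc_fhir_report` with `items_mapped`, `items_skipped`, `warnings`).
#' @export
questionnaire_to_metadata <- function(x) {
  res <- fhir_parse(x)
  if (!identical(res$resourceType, "Questionnaire")) {
    edc_error("NOT_A_QUESTIONNAIRE",
              sprintf("resourceType is '%s'", res$resourceType %||% "absent"))
  }

  acc <- new.env(parent = emptyenv())
  acc$widgets <- list()
  acc$lookups <- list()
  acc$taken <- character(0)
  acc$id_map <- character(0)   # raw (dotted) linkId path -> variable_id
  acc$skipped <- list()
  acc$warnings <- character(0)
  acc$encountered <- 0L
  acc$order <- 0L
  acc$pending_conditions <- list()

  skip <- function(link_id, reason) {
    acc$skipped[[length(acc$skipped) + 1L]] <-
      list(linkId = link_id, reason = reason)
  }

  walk <- function(items, prefix) {
    for (it in items) {
      link_id <- as.character(it$linkId %||% "")
      if (!nzchar(link_id)) {
        edc_error("MALFORMED_RESOURCE", "questionnaire item without linkId")
      }
      path <- if (nzchar(prefix)) paste(prefix, link_id, sep = ".") else link_id
      ty <- as.character(it$type %||% "")
      if (ty == "group") {
        walk(it$item %||% list(), path)
        next
      }
      acc$encountered <- acc$encountered + 1L
      if (ty == "display") { skip(path, "DISPLAY_ONLY"); next }
      input_type <- switch(ty,
        string = , text = "text",
        integer = "integer",
        decimal = "float",
        boolean = "checkbox",
        date = "date",
        time = "time",
        choice = NA,          # resolved below
        "open-choice" = NA,
        NULL)
      if (is.null(input_type)) { skip(path, paste0("UNSUPPORTED_TYPE:", ty)); next }

      vid <- sanitize_linkid(path, acc$taken)
      acc$taken <- c(acc$taken, vid)
      acc$id_map[path] <- vid
      acc$id_map[link_id] <- acc$id_map[link_id] %||% vid
      acc$order <- acc$order + 1L

      choices <- NULL
      lookup_id <- NULL
      if (ty %in% c("choice", "open-choice")) {
        opts <- it$answerOption %||% list()
        entries <- list()
        for (o in opts) {
          if (!is.null(o$valueCoding)) {
            entries[[length(entries) + 1L]] <-
              c(as.character(o$valueCoding$code),
                as.character(o$valueCoding$display %||% o$valueCoding$code))
          } else if (!is.null(o$valueString)) {
            entries[[length(entries) + 1L]] <-
              c(as.character(o$valueString), as.character(o$valueString))
          }
        }
        if (length(entries) == 0) { skip(path, "NO_ANSWER_OPTIONS"); next }
        if (ty == "choice") {
          input_type <- if (length(entries) <= 7) "radio" else "dropdown"
          if (length(entries) > 7) {
            acc$warnings <- c(acc$warnings,
              sprintf("item '%s': %d answer options, mapped to dropdown (radio threshold is 7)",
                      path, length(entries)))
          }
          choices <- entries
        } else {
          input_type <- "dropdown_search"
          lookup_id <- next_free_id(paste0(vid, "_lut"),
                                    vapply(acc$lookups, function(l) l$lookup_table_id,
                                           character(1)))
          acc$lookups[[length(acc$lookups) + 1L]] <-
            lookup_table(lookup_id, paste("Options of", path), entries)
        }
      }

      w <- widget_definition(vid, input_type,
                             label = as.character(it$text %||% link_id),
                             required = isTRUE(it$required),
                             choices = choices, lookup_table_id = lookup_id,
                             order_index = acc$order - 1L)
      acc$widgets[[length(acc$widgets) + 1L]] <- w

      ews <- it$enableWhen %||% list()
      if (length(ews) > 0) {
        acc$pending_conditions[[vid]] <-
          list(clauses = ews,
               behavior = as.character(it$enableBehavior %||% "all"),
               path = path)
      }
    }
  }
  walk(res$item %||% list(), "")

  # resolve enableWhen now that every mappable item has an id
  widgets <- acc$widgets
  names(widgets) <- vapply(widgets, function(w) w$variable_id, character(1))
  for (vid in names(acc$pending_conditions)) {
    pc <- acc$pending_conditions[[vid]]
    atoms <- list()
    dropped <- FALSE
    for (ew in pc$clauses) {
      q <- as.character(ew$question %||% "")
      ref <- acc$id_map[q]
      if (is.na(ref)) {
        acc$warnings <- c(acc$warnings,
          sprintf("item '%s': enableWhen references unmapped item '%s'; condition dropped",
                  pc$path, q))
        dropped <- TRUE
        break
      }
      opr <- as.character(ew$operator %||% "=")
      if (opr == "exists") {
        lit <- fhir_answer_literal(ew)
        atoms[[length(atoms) + 1L]] <-
          cnd_atom(unname(ref), if (isTRUE(lit)) "not_empty" else "is_empty")
      } else if (opr %in% names(FHIR_OP_MAP)) {
        lit <- fhir_answer_literal(ew)
        if (is.null(lit)) {
          acc$warnings <- c(acc$warnings,
            sprintf("item '%s': enableWhen clause without answer value; condition dropped",
                    pc$path))
          dropped <- TRUE
          break
        }
        atoms[[length(atoms) + 1L]] <-
          cnd_atom(unname(ref), unname(FHIR_OP_MAP[opr]), lit)
      } else {
        acc$warnings <- c(acc$warnings,
          sprintf("item '%s': unsupported enableWhen operator '%s'; condition dropped",
                  pc$path, opr))
        dropped <- TRUE
        break
      }
    }
    if (!dropped && length(atoms) > 0) {
      cond <- if (length(atoms) == 1) atoms[[1]]
        else if (identical(pc$behavior, "any")) do.call(cnd_any, atoms)
        else do.call(cnd_all, atoms)
      widgets[[vid]]$condition <- cond
    }
  }

  set_name <- as.character(res$title %||% res$id %||% "questionnaire")
  set <- variable_set(set_name, unname(widgets), acc$lookups)
  report <- structure(list(
    items_mapped = length(widgets),
    items_skipped = acc$skipped,
    warnings = acc$warnings,
    items_encountered = acc$encountered
  ), class = "edc_fhir_report")
  list(set = set, report = report)
}

#' @export
print.edc_fhir_report <- function(x, ...) {
  cat(sprintf("<FHIR import: %d mapped, %d skipped, %d warning(s)>\n",
              x$items_mapped, length(x$items_skipped), length(x$warnings)))
  invisible(x)
}

# flat linkId -> raw string answers of one QuestionnaireResponse
response_answers <- function(items, prefix = "") {
  out <- list()
  for (it in items) {
    link_id <- as.character(it$linkId %||% "")
    path <- if (nzchar(prefix)) paste(prefix, link_id, sep = ".") else link_id
    if (!is.null(it$item)) {
      out <- c(out, response_answers(it$item, path))
    }
    ans <- it$answer %||% list()
    if (length(ans) > 0) {
      a <- ans[[1]]
      raw <- if (!is.null(a$valueCoding)) as.character(a$valueCoding$code)
        else if (!is.null(a$valueString)) as.character(a$valueString)
        else if (!is.null(a$valueInteger)) sprintf("%d", as.integer(a$valueInteger))
        else if (!is.null(a$valueDecimal)) format(as.numeric(a$valueDecimal),
                                                 scientific = FALSE, trim = TRUE,
                                                 digits = 15)
        else if (!is.null(a$valueBoolean)) (if (isTRUE(a$valueBoolean)) "true" else "false")
        else if (!is.null(a$valueDate)) as.character(a$valueDate)
        else if (!is.null(a$valueTime)) substr(as.character(a$valueTime), 1, 5)
        else NULL
      if (!is.null(raw)) out[[path]] <- raw
    }
  }
  out
}

#' Import FHIR QuestionnaireResponses as submissions
#'
#' Turns a FHIR Bundle (or list of QuestionnaireResponse resources) into
#' submissions for one visit. Answers are matched to widgets by sanitized
#' linkId; `value[x]` entries are rendered to the canonical raw strings and
#' flow through the normal validation path — the bridge never writes to the
#' audit store directly. `status == "completed"` maps to the submission's
#' completeness assertion.
#'
#' Unmatched linkIds and answers whose code is not among the widget's
#' choices are skipped with reasons (`UNKNOWN_LINKID`,
#' `CODE_NOT_IN_CHOICES`).
#'
#' @param x path/JSON/list: a Bundle or a list of QuestionnaireResponses.
#' @param state an `edc_study_state` in deployment mode.
#' @param visit_id target visit.
#' @param pid_mapping named character vector mapping FHIR subject references
#'   to included PIDs.
#' @return list with `submissions` (list of `edc_submission`) and `report`
#'   (an `edc_fhir_report`).
#' @export
responses_to_records <- function(x, state, visit_id, pid_mapping) {
  if (state$mode != "deployment") {
    edc_error("NOT_DEPLOYED", "clinical data import requires deployment mode")
  }
  res <- fhir_parse(x)
  responses <- if (identical(res$resourceType, "Bundle")) {
    lapply(res$entry %||% list(), function(e) e$resource)
  } else if (identical(res$resourceType, "QuestionnaireResponse")) {
    list(res)
  } else if (is.null(res$resourceType)) {
    res  # a plain list of resources
  } else {
    edc_error("MALFORMED_RESOURCE",
              sprintf("cannot import resourceType '%s'", res$resourceType))
  }
  responses <- Filter(function(r) identical(r$resourceType, "QuestionnaireResponse"),
                      responses)

  # sanitized id map over the study's widgets
  known <- widget_ids(state$metadata)
  skipped <- list()
  warnings <- character(0)
  mapped <- 0L
  encountered <- 0L
  submissions <- list()

  for (r in responses) {
    subject <- as.character(r$subject$reference %||% r$subject$identifier$value %||% "")
    pid <- unname(pid_mapping[subject])
    if (is.null(pid) || is.na(pid)) {
      edc_error("UNKNOWN_PID",
                sprintf("no pid mapping for subject '%s'", subject))
    }
    if (!pid_exists(state, pid)) {
      edc_error("UNKNOWN_PID", sprintf("participant '%s' is not included", pid))
    }
    answers <- response_answers(r$item %||% list())
    values <- list()
    for (path in names(answers)) {
      encountered <- encountered + 1L
      vid <- sanitize_linkid(path)
      if (!vid %in% known) {
        skipped[[length(skipped) + 1L]] <-
          list(linkId = path, reason = "UNKNOWN_LINKID")
        next
      }
      w <- find_widget(state$metadata, vid)
      if (w$input_type %in% CHOICE_TYPES &&
          !answers[[path]] %in% w$choices$code) {
        skipped[[length(skipped) + 1L]] <-
          list(linkId = path, reason = "CODE_NOT_IN_CHOICES")
        next
      }
      values[[vid]] <- answers[[path]]
      mapped <- mapped + 1L
    }
    submissions[[length(submissions) + 1L]] <-
      submission(pid, visit_id, values,
                 submitted_by = "fhir_import",
                 complete = identical(r$status, "completed"))
  }

  report <- structure(list(items_mapped = mapped, items_skipped = skipped,
                           warnings = warnings,
                           items_encountered = encountered),
                      class = "edc_fhir_report")
  list(submissions = submissions, report = report)
}

#' Apply imported submissions through the normal entry path
#'
#' Convenience wrapper persisting the submissions returned by
#' [responses_to_records()] via [submit_entry()] (validating pass-through).
#'
#' @param state an `edc_study_state` in deployment mode.
#' @param submissions list of `edc_submission`.
#' @param actor actor token recorded on the stored rows.
#' @return invisibly, the list of validation reports.
#' @export
apply_submissions <- function(state, submissions, actor = "fhir_import") {
  reports <- lapply(submissions, function(s) {
    submit_entry(state, s$participant_id, s$visit_id, s$values, actor,
                 visit_instance = s$visit_instance,
                 complete = s$complete_flag)
  })
  invisible(reports)
}
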