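# Synthetic studies and entries at the scale of real multi-center use
# (hundreds of variables per participant, four-digit participant counts).
# Realism of the simulated values is not the goal — structural coverage is:
# every input type, skip logic, repeating visits, partial saves, amendments,
# deletions and multi-site PIDs.

#' Configuration for the synthetic-study generator
#'
#' @param seed integer driving all randomness; identical seeds give
#'   identical studies, entries and audit trails.
#' @param n_visits number of visits (>= 1); the last visit repeats when
#'   `n_visits >= 2`.
#' @param n_widgets number of widgets; with `n_widgets >= 9` every input
#'   type occurs at least once.
#' @param type_mix named proportions over the nine input types (must sum to
#'   1); the default spreads mass across all types with extra weight on
#'   text/numeric fields, as typical for clinical case report forms.
#' @param condition_density fraction of widgets given a display condition.
#' @param n_participants number of participants to include.
#' @param missingness fraction of non-required visible fields left empty.
#' @param n_sites number of study sites contributing participants.
#' @param required_fraction fraction of widgets marked required.
#' @param participant_centered_fraction fraction of widgets captured
#'   independently of visits.
#' @param partial_fraction fraction of visit forms saved incomplete.
#' @param amendment_fraction fraction of stored records later amended.
#' @param deletion_fraction fraction of stored records later soft-deleted.
#' @param repeat_fraction probability of a second instance of a repeating
#'   visit per participant.
#' @return a validated list of class `edc_demo_config`.
#' @export
demo_config <- function(seed = 1L, n_visits = 2L, n_widgets = 30L,
                        type_mix = NULL, condition_density = 0.2,
                        n_participants = 100L, missingness = 0.1,
                        n_sites = 2L, required_fraction = 0.3,
                        participant_centered_fraction = 0.05,
                        partial_fraction = 0.05,
                        amendment_fraction = 0.1,
                        deletion_fraction = 0.02,
                        repeat_fraction = 0.2) {
  if (is.null(type_mix)) {
    type_mix <- c(text = 0.2, integer = 0.15, float = 0.15, checkbox = 0.1,
                  time = 0.05, date = 0.1, radio = 0.1, dropdown = 0.1,
                  dropdown_search = 0.05)
  }
  if (!setequal(names(type_mix), INPUT_TYPES)) {
    edc_error("INVALID_CONFIG", "type_mix must name all nine input types")
  }
  if (abs(sum(type_mix) - 1) > 1e-8 || any(type_mix < 0)) {
    edc_error("INVALID_CONFIG", "type_mix proportions must be >= 0 and sum to 1")
  }
  fracs <- c(condition_density, missingness, required_fraction,
             participant_centered_fraction, partial_fraction,
             amendment_fraction, deletion_fraction, repeat_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    edc_error("INVALID_CONFIG", "fractions must lie in [0, 1]")
  }
  if (n_visits < 1 || n_widgets < 1 || n_participants < 0 || n_sites < 1) {
    edc_error("INVALID_CONFIG", "counts must be positive")
  }
  structure(list(seed = as.integer(seed), n_visits = as.integer(n_visits),
                 n_widgets = as.integer(n_widgets),
                 type_mix = type_mix[INPUT_TYPES],
                 condition_density = condition_density,
                 n_participants = as.integer(n_participants),
                 missingness = missingness, n_sites = as.integer(n_sites),
                 required_fraction = required_fraction,
                 participant_centered_fraction = participant_centered_fraction,
                 partial_fraction = partial_fraction,
                 amendment_fraction = amendment_fraction,
                 deletion_fraction = deletion_fraction,
                 repeat_fraction = repeat_fraction),
            class = "edc_demo_config")
}

#' Bundled miniature diagnosis vocabulary
#'
#' A 25-entry ICD-10-style lookup table shipped with the package, backing
#' the generator's searchable dropdowns.
#'
#' @return an `edc_lookup`.
#' @export
demo_lookup_table <- function() {
  path <- system.file("extdata", "icd10_demo.csv", package = "edcforge",
                      mustWork = TRUE)
  lookup_table("icd10_demo", "Demo diagnosis vocabulary (ICD-10 style)",
               read_csv_strict(path))
}

DEMO_WORDS <- c("symptom", "onset", "severity", "pain", "history", "score",
                "medication", "dose", "lab", "value", "finding", "imaging",
                "assessment", "outcome", "visit", "blood", "pressure",
                "temperature", "weight", "pulse", "oxygen", "therapy",
                "intervention", "status", "note")

demo_label <- function() {
  paste(tools::toTitleCase(paste(sample(DEMO_WORDS, 2), collapse = " ")))
}

# a type-correct condition atom on an already-defined widget
demo_condition_atom <- function(ref) {
  switch(ref$input_type,
    checkbox = cnd_atom(ref$variable_id, "eq", TRUE),
    integer = cnd_atom(ref$variable_id, "ge", as.numeric(sample(10:60, 1))),
    float = cnd_atom(ref$variable_id, "le", as.numeric(sample(50:400, 1))),
    text = cnd_atom(ref$variable_id, "not_empty"),
    date = cnd_atom(ref$variable_id, "ge", "2023-06-01"),
    time = cnd_atom(ref$variable_id, "ge", "12:00"),
    radio = ,
    dropdown = {
      codes <- ref$choices$code
      if (length(codes) > 2 && runif(1) < 0.5) {
        cnd_atom(ref$variable_id, "in_set", sample(codes, 2))
      } else {
        cnd_atom(ref$variable_id, "eq", sample(codes, 1))
      }
    },
    dropdown_search = cnd_atom(ref$variable_id, "not_empty")
  )
}

#' Generate a complete synthetic study
#'
#' Deterministic in `cfg$seed`. The study has `n_visits` visits (baseline
#' first, the last one repeating when there are at least two), `n_widgets`
#' widgets covering every input type once before following `type_mix`, a
#' fraction of participant-centered widgets, the bundled diagnosis
#' vocabulary behind searchable dropdowns, and display conditions that only
#' reference earlier-ordered widgets of the same form scope — acyclic by
#' construction. The result always passes [validate_study_metadata()].
#'
#' @param cfg an `edc_demo_config`.
#' @return an `edc_study_metadata`.
#' @export
generate_demo_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "edc_demo_config"))
  withr::with_seed(cfg$seed, {
    visits <- lapply(seq_len(cfg$n_visits), function(i) {
      visit_definition(
        visit_id = sprintf("visit_%02d", i),
        title = if (i == 1) "Baseline" else sprintf("Follow-up %d", i - 1),
        order_index = i - 1L,
        repeating = (i == cfg$n_visits && cfg$n_visits >= 2),
        mobile = (i == 1)
      )
    })
    vids <- vapply(visits, function(v) v$visit_id, character(1))

    types <- if (cfg$n_widgets >= length(INPUT_TYPES)) {
      c(INPUT_TYPES,
        sample(INPUT_TYPES, cfg$n_widgets - length(INPUT_TYPES),
               replace = TRUE, prob = cfg$type_mix))
    } else {
      sample(INPUT_TYPES, cfg$n_widgets, replace = TRUE, prob = cfg$type_mix)
    }
    types <- sample(types)  # shuffle so conditions can reference any type

    lut <- demo_lookup_table()
    need_lut <- any(types == "dropdown_search")

    n_pc <- round(cfg$participant_centered_fraction * cfg$n_widgets)
    pc_idx <- if (n_pc > 0) sample(cfg$n_widgets, n_pc) else integer(0)

    widgets <- vector("list", cfg$n_widgets)
    for (i in seq_len(cfg$n_widgets)) {
      ty <- types[i]
      assigned <- if (i %in% pc_idx) character(0)
        else vids[1 + (i - 1) %% cfg$n_visits]
      choices <- NULL
      if (ty %in% c("radio", "dropdown")) {
        k <- sample(2:5, 1)
        choices <- lapply(seq_len(k), function(j) {
          c(sprintf("c%d", j), tools::toTitleCase(sample(DEMO_WORDS, 1)))
        })
      }
      widgets[[i]] <- widget_definition(
        variable_id = sprintf("var_%03d_%s", i, ty),
        input_type = ty,
        label = demo_label(),
        required = runif(1) < cfg$required_fraction,
        visit_ids = assigned,
        choices = choices,
        lookup_table_id = if (ty == "dropdown_search") lut$lookup_table_id,
        order_index = i - 1L,
        units = if (ty %in% c("integer", "float") && runif(1) < 0.5)
          sample(c("mg/dl", "mmHg", "kg", "bpm", "%"), 1),
        help_text = if (runif(1) < 0.2) "Enter as documented in the chart."
      )
    }

    # display conditions: reference an earlier widget of the same scope
    # (same visit or participant-centered), keeping the graph acyclic and
    # evaluable within one form
    scope_of <- function(w) if (length(w$visit_ids) == 0) "pc" else w$visit_ids[1]
    for (i in seq_len(cfg$n_widgets)) {
      if (i == 1 || runif(1) >= cfg$condition_density) next
      sc <- scope_of(widgets[[i]])
      cands <- Filter(function(j) {
        s <- scope_of(widgets[[j]])
        s == sc || s == "pc"
      }, seq_len(i - 1L))
      if (length(cands) == 0) next
      ref1 <- widgets[[cands[sample.int(length(cands), 1)]]]
      cond <- demo_condition_atom(ref1)
      if (length(cands) > 1 && runif(1) < 0.25) {
        ref2 <- widgets[[cands[sample.int(length(cands), 1)]]]
        if (!identical(ref2$variable_id, ref1$variable_id)) {
          comb <- if (runif(1) < 0.5) cnd_all else cnd_any
          cond <- comb(cond, demo_condition_atom(ref2))
        }
      }
      widgets[[i]]$condition <- cond
    }

    study_metadata(
      study_id = sprintf("demo_study_%04d", cfg$seed %% 10000L),
      title = sprintf("Synthetic study (seed %d)", cfg$seed),
      visits = visits,
      widgets = widgets,
      lookup_tables = if (need_lut) list(lut) else list(),
      metadata_version = 1L
    )
  })
}

# plausible raw value for one widget type
demo_raw_value <- function(w, lut) {
  switch(w$input_type,
    text = paste(sample(DEMO_WORDS, sample(1:3, 1)), collapse = " "),
    integer = sprintf("%d", sample(0:120, 1)),
    float = format(round(runif(1, 0, 500), 2), scientific = FALSE, trim = TRUE,
                   digits = 15),
    checkbox = sample(c("true", "false"), 1),
    date = format(as.Date("2023-01-01") + sample(0:364, 1), "%Y-%m-%d"),
    time = sprintf("%02d:%02d", sample(0:23, 1), sample(0:59, 1)),
    radio = ,
    dropdown = sample(w$choices$code, 1),
    dropdown_search = sample(lut$entries$code, 1)
  )
}

# fill one form in order, honoring skip logic and missingness; returns a
# named character vector of raw values
demo_fill_form <- function(study, visit_id, cfg, lut, ctx = list(),
                           partial = FALSE) {
  values <- character(0)
  for (w in widgets_for_visit(study, visit_id)) {
    if (!evaluate_condition(w$condition, ctx)) next  # hidden: leave empty
    if (partial && runif(1) < 0.5) next
    if (!w$required && runif(1) < cfg$missingness) next
    raw <- demo_raw_value(w, lut)
    values[w$variable_id] <- raw
    v <- coerce_value(raw, w, lut)
    if (!is_coercion_failure(v)) ctx[[w$variable_id]] <- v
  }
  attr(values, "ctx") <- ctx
  values
}

#' Simulate a full data-capture campaign on a fresh deployment
#'
#' Builds a study state from `study`, activates deployment, includes
#' `cfg$n_participants` participants across `cfg$n_sites` sites and fills
#' their forms: participant-centered data first, then every visit (with a
#' second instance of repeating visits for a `repeat_fraction` of
#' participants, and partial saves for a `partial_fraction` of forms).
#' Afterwards a fraction of stored records receives amendments and
#' soft-deletions to exercise the audit chain. Hidden widgets are always
#' left empty and missingness is only injected into non-required fields, so
#' complete submissions validate by construction. Fully deterministic in
#' `cfg$seed`.
#'
#' @param study an `edc_study_metadata` (typically from
#'   [generate_demo_metadata()]).
#' @param cfg an `edc_demo_config`.
#' @param progress print progress every 200 participants?
#' @return list with `state` (the populated `edc_study_state`), `log`
#'   (data frame of operations) and `counts` (named operation totals).
#' @export
simulate_entries <- function(study, cfg, progress = FALSE) {
  stopifnot(inherits(study, "edc_study_metadata"),
            inherits(cfg, "edc_demo_config"))
  rep <- validate_study_metadata(study)
  if (!report_ok(rep)) {
    edc_error("INVALID_CONFIG", "study must pass validation",
              data = list(report = rep))
  }
  lut <- if (length(study$lookup_tables) > 0) study$lookup_tables[[1]] else NULL
  withr::with_seed(cfg$seed + 1L, {
    state <- study_state(study, origin_id = "sim",
                         clock = fixed_clock("2024-01-01T08:00:00.000Z", 250))
    activate_deployment(state, "setup")

    sites <- sprintf("site_%02d", seq_len(cfg$n_sites))
    has_pc <- length(widgets_for_visit(study, PARTICIPANT_VISIT)) > 0
    log <- list()
    note <- function(op, pid, visit, instance) {
      log[[length(log) + 1L]] <<- c(op = op, pid = pid, visit = visit,
                                    instance = as.character(instance))
    }

    for (i in seq_len(cfg$n_participants)) {
      p <- include_participant(state, sites[1 + (i - 1) %% cfg$n_sites], "sim")
      note("include", p$pid, "", 1L)
      if (has_pc) {
        vals <- demo_fill_form(study, PARTICIPANT_VISIT, cfg, lut)
        submit_entry(state, p$pid, PARTICIPANT_VISIT, vals, "sim")
        note("enter", p$pid, PARTICIPANT_VISIT, 1L)
      }
      pc_ctx <- entry_values(state, p$pid, PARTICIPANT_VISIT, 1L)
      for (v in study$visits) {
        insts <- 1L
        if (v$repeating && runif(1) < cfg$repeat_fraction) insts <- 1:2
        for (k in insts) {
          partial <- runif(1) < cfg$partial_fraction
          vals <- demo_fill_form(study, v$visit_id, cfg, lut, ctx = pc_ctx,
                                 partial = partial)
          submit_entry(state, p$pid, v$visit_id, vals, "sim",
                       visit_instance = k, complete = !partial)
          note(if (partial) "enter_partial" else "enter", p$pid, v$visit_id, k)
        }
      }
      if (progress && i %% 200 == 0) {
        message(sprintf("simulated %d/%d participants", i, cfg$n_participants))
      }
    }

    # amendments and deletions on the stored clinical records; amendments
    # only touch widgets that control no other widget's visibility, so a
    # value change cannot expose an empty required field
    controller_ids <- unique(unlist(lapply(study$widgets, function(w) {
      condition_vars(w$condition)
    })))
    rec_keys <- sort(ls(state$entry_index))
    n_amend <- round(cfg$amendment_fraction * length(rec_keys))
    if (n_amend > 0) {
      for (key in sample(rec_keys, n_amend)) {
        parts <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
        pid <- parts[1]; vid <- parts[2]; inst <- as.integer(parts[3])
        ws <- widgets_for_visit(study, vid)
        ctx <- entry_values(state, pid, vid, inst)
        # change one currently visible widget's value
        vis <- Filter(function(w) {
          !w$variable_id %in% controller_ids &&
            evaluate_condition(w$condition, ctx)
        }, ws)
        if (length(vis) == 0) next
        w <- vis[[sample.int(length(vis), 1)]]
        prev <- current_entry_row(state, pid, vid, inst)
        if (is.null(prev)) next
        submit_entry(state, pid, vid,
                     stats::setNames(list(demo_raw_value(w, lut)),
                                     w$variable_id),
                     "sim_amend", visit_instance = inst,
                     complete = isTRUE(prev$payload$complete))
        note("amend", pid, vid, inst)
      }
    }
    n_del <- round(cfg$deletion_fraction * length(rec_keys))
    if (n_del > 0) {
      for (key in sample(rec_keys, n_del)) {
        rid <- state$entry_index[[key]]
        head <- record_head(state$store, rid)
        if (is.null(head) || head$deleted) next
        soft_delete(state$store, rid, "sim_delete")
        parts <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
        note("delete", parts[1], parts[2], as.integer(parts[3]))
      }
    }

    log_df <- as.data.frame(do.call(rbind, log), stringsAsFactors = FALSE)
    counts <- table(log_df$op)
    list(state = state, log = log_df,
         counts = stats::setNames(as.integer(counts), names(counts)))
  })
}
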