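# shared fixtures and independent oracles for the test suite

expect_edc_error <- function(expr, code) {
  err <- tryCatch({ expr; NULL }, edc_error = function(e) e)
  expect_false(is.null(err),
               label = sprintf("expected an edc_error [%s]", code))
  if (!is.null(err)) expect_identical(edc_error_code(err), code)
  invisible(err)
}

# a small hand-built study used across module tests
tiny_study <- function() {
  study_metadata(
    "tiny_trial", "Tiny trial",
    visits = list(
      visit_definition("baseline", "Baseline", 0L, mobile = TRUE),
      visit_definition("followup", "Follow-up", 1L, repeating = TRUE)
    ),
    widgets = list(
      widget_definition("age", "integer", "Age", required = TRUE,
                        visit_ids = "baseline", order_index = 0L,
                        units = "years"),
      widget_definition("sex", "radio", "Sex", required = TRUE,
                        visit_ids = "baseline",
                        choices = list(c("f", "Female"), c("m", "Male")),
                        order_index = 1L),
      widget_definition("pregnant", "checkbox", "Currently pregnant",
                        visit_ids = "baseline",
                        condition = "sex eq \"f\"", order_index = 2L),
      widget_definition("dx", "dropdown_search", "Main diagnosis",
                        visit_ids = "baseline",
                        lookup_table_id = "icd10_demo", order_index = 3L),
      widget_definition("note", "text", "Clinical note",
                        visit_ids = "followup", order_index = 4L),
      widget_definition("meds", "text", "Current medication",
                        order_index = 5L)  # participant-centered
    ),
    lookup_tables = list(demo_lookup_table())
  )
}

deployed_tiny_state <- function(clock = fixed_clock()) {
  state <- study_state(tiny_study(), origin_id = "muc", clock = clock)
  activate_deployment(state, "setup")
  state
}

# ---- independent condition oracle -------------------------------------------

# brute-force recursive evaluator, written against the documented semantics
# and independent of the engine implementation
oracle_eval <- function(expr, values) {
  if (is.null(expr)) return(TRUE)
  if (expr$kind == "all") {
    res <- TRUE
    for (ch in expr$children) res <- res && oracle_eval(ch, values)
    return(res)
  }
  if (expr$kind == "any") {
    res <- FALSE
    for (ch in expr$children) res <- res || oracle_eval(ch, values)
    return(res)
  }
  v <- values[[expr$variable_id]]
  miss <- is.null(v) || length(v) != 1 || is.na(v) ||
    (is.character(v) && identical(v, ""))
  if (expr$op == "is_empty") return(miss)
  if (expr$op == "not_empty") return(!miss)
  if (miss) return(FALSE)
  lit <- expr$literal
  if (expr$op == "in_set") return(as.character(v) %in% lit)
  if (is.numeric(lit)) v <- as.numeric(v)
  cmp <- switch(expr$op,
                eq = v == lit, ne = v != lit, lt = v < lit, le = v <= lit,
                gt = v > lit, ge = v >= lit)
  isTRUE(cmp)
}

# random condition trees over a fixed pool of typed variables
random_tree_vars <- list(
  list(id = "num_a", type = "numeric"),
  list(id = "num_b", type = "numeric"),
  list(id = "str_a", type = "character"),
  list(id = "str_b", type = "character"),
  list(id = "flag_a", type = "logical")
)

random_atom <- function() {
  v <- random_tree_vars[[sample.int(length(random_tree_vars), 1)]]
  if (v$type == "numeric") {
    op <- sample(c("eq", "ne", "lt", "le", "gt", "ge", "is_empty", "not_empty"), 1)
    lit <- if (op %in% c("is_empty", "not_empty")) NULL else
      as.numeric(sample(0:10, 1))
  } else if (v$type == "character") {
    op <- sample(c("eq", "ne", "in_set", "is_empty", "not_empty"), 1)
    lit <- if (op %in% c("is_empty", "not_empty")) NULL
      else if (op == "in_set") sample(letters[1:5], sample(1:3, 1))
      else sample(letters[1:5], 1)
  } else {
    op <- sample(c("eq", "ne", "is_empty", "not_empty"), 1)
    lit <- if (op %in% c("is_empty", "not_empty")) NULL else
      sample(c(TRUE, FALSE), 1)
  }
  cnd_atom(v$id, op, lit)
}

random_tree <- function(depth = 3) {
  if (depth <= 0 || runif(1) < 0.4) return(random_atom())
  n <- sample(0:3, 1)
  children <- lapply(seq_len(n), function(i) random_tree(depth - 1))
  if (runif(1) < 0.5) do.call(cnd_all, children) else do.call(cnd_any, children)
}

random_values <- function() {
  vals <- list()
  for (v in random_tree_vars) {
    r <- runif(1)
    if (r < 0.3) next  # unanswered
    vals[[v$id]] <- if (r < 0.35) NA
      else switch(v$type,
                  numeric = as.numeric(sample(0:10, 1)),
                  character = sample(c(letters[1:5], ""), 1),
                  logical = sample(c(TRUE, FALSE), 1))
  }
  vals
}

# ---- typed value fuzzers ----------------------------------------------------

fuzz_widget <- function(type) {
  widget_definition(paste0("fuzz_", gsub("_", "", type)), type,
                    label = paste("fuzz", type),
                    choices = if (type %in% c("radio", "dropdown"))
                      list(c("c1", "One"), c("c2", "Two"), c("c3", "Three")),
                    lookup_table_id = if (type == "dropdown_search") "icd10_demo")
}

fuzz_value <- function(type, lut) {
  switch(type,
    text = {  # the text domain is trimmed, non-empty unicode
      s <- trimws(paste(sample(c(letters, " ", ",", "\"", "é"),
                               sample(1:12, 1), replace = TRUE),
                        collapse = ""))
      if (nzchar(s)) s else "x"
    },
    integer = sample(-5000:5000, 1),
    float = round(runif(1, -1000, 1000), sample(0:4, 1)),
    checkbox = sample(c(TRUE, FALSE), 1),
    date = format(as.Date("2020-01-01") + sample(0:1500, 1), "%Y-%m-%d"),
    time = sprintf("%02d:%02d", sample(0:23, 1), sample(0:59, 1)),
    radio = ,
    dropdown = sample(c("c1", "c2", "c3"), 1),
    dropdown_search = sample(lut$entries$code, 1)
  )
}
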