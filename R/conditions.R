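#' Skip-logic condition expressions
#'
#' Display conditions ("skip logic") decide when a widget is shown. A
#' condition is a tree of `ALL(...)` / `ANY(...)` combinators over atoms of
#' the form `variable OP literal`. The canonical serialized form is, e.g.,
#'
#' ```
#' ALL(age ge 18, ANY(sex eq "f", dx in_set {"J45", "J44.0"}), note not_empty)
#' ```
#'
#' Operators: `eq`, `ne`, `lt`, `le`, `gt`, `ge`, `in_set`, `is_empty`,
#' `not_empty`. String literals are double-quoted (with `\"` and `\\`
#' escapes), numbers are plain decimals, booleans are `true`/`false`, and
#' `in_set` takes a brace-enclosed set of quoted codes. `is_empty` and
#' `not_empty` take no literal.
#'
#' @name conditions
NULL

CONDITION_OPS <- c("eq", "ne", "lt", "le", "gt", "ge", "in_set",
                   "is_empty", "not_empty")

new_condition <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "edc_condition")
}

#' @rdname conditions
#' @param variable_id identifier of the referenced widget.
#' @param op one of the condition operators.
#' @param literal comparison literal: a single string, number or logical, or
#'   a character vector of codes for `in_set`; omitted for `is_empty` /
#'   `not_empty`.
#' @return an object of class `edc_condition`.
#' @export
cnd_atom <- function(variable_id, op, literal = NULL) {
  if (!is_token(variable_id)) {
    edc_error("BAD_CONDITION", sprintf("not a valid variable id: %s", variable_id))
  }
  if (!op %in% CONDITION_OPS) {
    edc_error("BAD_CONDITION", sprintf("unknown operator: %s", op))
  }
  if (op %in% c("is_empty", "not_empty")) {
    literal <- NULL
  } else if (op == "in_set") {
    if (!is.character(literal) || length(literal) < 1) {
      edc_error("BAD_CONDITION", "in_set needs a character vector of codes")
    }
  } else {
    if (length(literal) != 1 || is.na(literal)) {
      edc_error("BAD_CONDITION", sprintf("operator %s needs a scalar literal", op))
    }
    if (is.numeric(literal)) literal <- as.numeric(literal)
    else if (!is.character(literal) && !is.logical(literal)) {
      edc_error("BAD_CONDITION", "literal must be string, number or boolean")
    }
  }
  new_condition("atom", variable_id = variable_id, op = op, literal = literal)
}

#' @rdname conditions
#' @param ... child conditions.
#' @export
cnd_all <- function(...) {
  children <- list(...)
  stopifnot(all(vapply(children, inherits, logical(1), "edc_condition")))
  new_condition("all", children = children)
}

#' @rdname conditions
#' @export
cnd_any <- function(...) {
  children <- list(...)
  stopifnot(all(vapply(children, inherits, logical(1), "edc_condition")))
  new_condition("any", children = children)
}

#' @export
print.edc_condition <- function(x, ...) {
  cat("<condition> ", serialize_condition(x), "\n", sep = "")
  invisible(x)
}

# all variable ids referenced anywhere in a condition tree
condition_vars <- function(expr) {
  if (is.null(expr)) return(character(0))
  if (expr$kind == "atom") return(expr$variable_id)
  unique(unlist(lapply(expr$children, condition_vars)))
}

# ---- serialization ----------------------------------------------------------

quote_literal <- function(x) {
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) {
    s <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
    return(s)
  }
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
}

#' Serialize a condition to its canonical string form
#'
#' @param expr an `edc_condition`, or `NULL` (serialized as the empty string).
#' @return a single string; `parse_condition()` is its exact inverse.
#' @export
serialize_condition <- function(expr) {
  if (is.null(expr)) return("")
  switch(expr$kind,
    atom = {
      if (expr$op %in% c("is_empty", "not_empty")) {
        paste(expr$variable_id, expr$op)
      } else if (expr$op == "in_set") {
        paste0(expr$variable_id, " in_set {",
               paste(vapply(expr$literal, quote_literal, character(1)),
                     collapse = ", "), "}")
      } else {
        paste(expr$variable_id, expr$op, quote_literal(expr$literal))
      }
    },
    all = paste0("ALL(", paste(vapply(expr$children, serialize_condition,
                                      character(1)), collapse = ", "), ")"),
    any = paste0("ANY(", paste(vapply(expr$children, serialize_condition,
                                      character(1)), collapse = ", "), ")")
  )
}

# ---- parser -----------------------------------------------------------------

tokenize_condition <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", "{", "}", ",")) {
      tokens[[length(tokens) + 1L]] <- list(type = "punct", value = ch)
      i <- i + 1L
    } else if (ch == '"') {
      j <- i + 1L
      out <- character(0)
      closed <- FALSE
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") {
          nxt <- substr(text, j + 1L, j + 1L)
          if (!nxt %in% c('"', "\\")) {
            edc_error("CONDITION_SYNTAX", sprintf("bad escape at %d", j))
          }
          out <- c(out, nxt); j <- j + 2L
        } else if (cj == '"') { closed <- TRUE; j <- j + 1L; break }
        else { out <- c(out, cj); j <- j + 1L }
      }
      if (!closed) edc_error("CONDITION_SYNTAX", "unterminated string literal")
      tokens[[length(tokens) + 1L]] <- list(type = "string",
                                            value = paste(out, collapse = ""))
      i <- j
    } else if (grepl("[0-9+.-]", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?",
                              substr(text, i, n)))
      if (length(m) == 0 || !nzchar(m)) {
        edc_error("CONDITION_SYNTAX", sprintf("bad number at %d", i))
      }
      tokens[[length(tokens) + 1L]] <- list(type = "number",
                                            value = as.numeric(m))
      i <- i + nchar(m)
    } else if (grepl("[A-Za-z_]", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(text, i, n)))
      tokens[[length(tokens) + 1L]] <- list(type = "ident", value = m)
      i <- i + nchar(m)
    } else {
      edc_error("CONDITION_SYNTAX", sprintf("unexpected character '%s' at %d", ch, i))
    }
  }
  tokens
}

#' Parse the canonical condition string form
#'
#' @param text a condition string as produced by [serialize_condition()];
#'   the empty string parses to `NULL` (no condition).
#' @return an `edc_condition` or `NULL`.
#' @export
parse_condition <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) return(NULL)
  tokens <- tokenize_condition(text)
  pos <- new.env(parent = emptyenv())
  pos$i <- 1L

  peek <- function() if (pos$i <= length(tokens)) tokens[[pos$i]] else NULL
  advance <- function() { t <- peek(); pos$i <- pos$i + 1L; t }
  expect_punct <- function(p) {
    t <- advance()
    if (is.null(t) || t$type != "punct" || t$value != p) {
      edc_error("CONDITION_SYNTAX", sprintf("expected '%s'", p))
    }
  }

  parse_literal <- function() {
    t <- advance()
    if (is.null(t)) edc_error("CONDITION_SYNTAX", "expected literal")
    if (t$type == "string") return(t$value)
    if (t$type == "number") return(t$value)
    if (t$type == "ident" && t$value %in% c("true", "false")) {
      return(t$value == "true")
    }
    edc_error("CONDITION_SYNTAX", "expected literal")
  }

  parse_expr <- function() {
    t <- peek()
    if (is.null(t)) edc_error("CONDITION_SYNTAX", "unexpected end of input")
    if (t$type == "ident" && t$value %in% c("ALL", "ANY")) {
      combin <- advance()$value
      expect_punct("(")
      children <- list()
      t2 <- peek()
      if (!is.null(t2) && !(t2$type == "punct" && t2$value == ")")) {
        repeat {
          children[[length(children) + 1L]] <- parse_expr()
          t2 <- peek()
          if (!is.null(t2) && t2$type == "punct" && t2$value == ",") {
            advance()
          } else break
        }
      }
      expect_punct(")")
      if (combin == "ALL") do.call(cnd_all, children)
      else do.call(cnd_any, children)
    } else if (t$type == "ident") {
      var <- advance()$value
      opt <- advance()
      if (is.null(opt) || opt$type != "ident" || !opt$value %in% CONDITION_OPS) {
        edc_error("CONDITION_SYNTAX", sprintf("expected operator after '%s'", var))
      }
      op <- opt$value
      if (op %in% c("is_empty", "not_empty")) {
        cnd_atom(var, op)
      } else if (op == "in_set") {
        expect_punct("{")
        lits <- character(0)
        repeat {
          lits <- c(lits, as.character(parse_literal()))
          t2 <- peek()
          if (!is.null(t2) && t2$type == "punct" && t2$value == ",") advance()
          else break
        }
        expect_punct("}")
        cnd_atom(var, "in_set", lits)
      } else {
        cnd_atom(var, op, parse_literal())
      }
    } else {
      edc_error("CONDITION_SYNTAX", "expected condition")
    }
  }

  out <- parse_expr()
  if (pos$i <= length(tokens)) {
    edc_error("CONDITION_SYNTAX", "trailing input after condition")
  }
  out
}

# ---- evaluation -------------------------------------------------------------

value_missing <- function(v) {
  is.null(v) || length(v) != 1 || is.na(v) ||
    (is.character(v) && !nzchar(v))
}

#' Evaluate a condition against current values
#'
#' Pure function of the expression and the supplied typed values. Atoms that
#' reference a missing or unanswered variable evaluate to `FALSE`, except
#' `is_empty` which evaluates to `TRUE`. `ALL()` over no children is `TRUE`;
#' `ANY()` over no children is `FALSE`. Ordered comparisons on dates and
#' times compare the canonical ISO strings, whose lexicographic order equals
#' chronological order.
#'
#' @param expr an `edc_condition`, or `NULL` (always `TRUE`).
#' @param values named list mapping variable ids to typed values (`NA`,
#'   `NULL` or absence meaning unanswered).
#' @return a single logical.
#' @export
evaluate_condition <- function(expr, values = list()) {
  if (is.null(expr)) return(TRUE)
  switch(expr$kind,
    all = all(vapply(expr$children, evaluate_condition, logical(1), values)),
    any = any(vapply(expr$children, evaluate_condition, logical(1), values)),
    atom = {
      v <- values[[expr$variable_id]]
      missing <- value_missing(v)
      if (expr$op == "is_empty") return(missing)
      if (expr$op == "not_empty") return(!missing)
      if (missing) return(FALSE)
      lit <- expr$literal
      if (expr$op == "in_set") return(as.character(v) %in% lit)
      if (is.numeric(lit)) v <- suppressWarnings(as.numeric(v))
      else if (is.logical(lit)) v <- as_flag(v)
      else v <- as.character(v)
      if (length(v) != 1 || is.na(v)) return(FALSE)
      switch(expr$op,
        eq = isTRUE(v == lit),
        ne = isTRUE(v != lit),
        lt = isTRUE(v < lit),
        le = isTRUE(v <= lit),
        gt = isTRUE(v > lit),
        ge = isTRUE(v >= lit)
      )
    }
  )
}
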