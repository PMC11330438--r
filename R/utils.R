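#' @importFrom stats runif
#' @importFrom utils read.csv unzip head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a structured engine error
#'
#' All recoverable failures in the package are signalled as conditions of
#' class `edc_error` carrying a machine-readable `code` (e.g. `UNKNOWN_VISIT`,
#' `NOT_DEPLOYED`). Callers — including the command-line interface — dispatch
#' on the code rather than on message text.
#'
#' @param code machine-readable error code, upper snake case.
#' @param message human-readable message.
#' @param data optional list of structured details (e.g. a validation report).
#' @keywords internal
edc_error <- function(code, message, data = list()) {
  cond <- structure(
    class = c(paste0("edc_error_", tolower(code)), "edc_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, message),
         call = sys.call(-1), code = code, data = data)
  )
  stop(cond)
}

#' Extract the machine-readable code from an edc_error condition
#' @param e a condition object.
#' @return character code, or `NA` if not an edc_error.
#' @export
edc_error_code <- function(e) {
  if (inherits(e, "edc_error")) e$code else NA_character_
}

# ---- validation reports -----------------------------------------------------

new_report_entry <- function(variable_id, code, message, severity = "error") {
  data.frame(variable_id = variable_id %||% NA_character_,
             code = code, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Build a validation report
#'
#' A validation report is a data frame with columns `variable_id`, `code`,
#' `severity` and `message`. Problems are always reported, never raised:
#' an empty report (or one containing only warnings) means the checked
#' object is admissible.
#'
#' @param entries a list of report-entry data frames, or NULL for an empty
#'   (passing) report.
#' @return an object of class `edc_validation_report`.
#' @export
validation_report <- function(entries = NULL) {
  if (is.null(entries) || length(entries) == 0) {
    df <- data.frame(variable_id = character(), code = character(),
                     severity = character(), message = character(),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, entries)
    rownames(df) <- NULL
  }
  class(df) <- c("edc_validation_report", "data.frame")
  df
}

#' Does a validation report pass?
#'
#' @param report an `edc_validation_report`.
#' @param warnings_ok if `TRUE` (default) warning-severity entries do not
#'   fail the report.
#' @return logical.
#' @export
report_ok <- function(report, warnings_ok = TRUE) {
  if (nrow(report) == 0) return(TRUE)
  if (warnings_ok) !any(report$severity == "error") else FALSE
}

#' @export
print.edc_validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation report: ok>\n")
  } else {
    cat(sprintf("<validation report: %d entr%s>\n", nrow(x),
                if (nrow(x) == 1) "y" else "ies"))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

report_codes <- function(report) unique(report$code)

# ---- identifier charsets ----------------------------------------------------

# variable/visit/study identifiers: lowercase snake case, CSV-column safe
is_token <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) &&
    grepl("^[a-z][a-z0-9_]{0,63}$", x)
}

# vocabulary codes (choice codes, lookup codes): real dictionaries such as
# ICD-10 use upper case and dots ("J45.0"), so codes get a wider charset than
# identifiers while staying quoting-free in CSV.
is_code <- function(x) {
  is.character(x) && !is.na(x) && grepl("^[A-Za-z0-9][A-Za-z0-9_.-]{0,63}$", x)
}

# ---- canonical JSON ---------------------------------------------------------

canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && length(x) > 0) x <- x[order(nm)]
    lapply(x, canonicalize)
  } else x
}

# deterministic byte representation of a payload: keys sorted recursively,
# scalars unboxed; used for storage, digests and conflict detection.
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(canonicalize(x), auto_unbox = TRUE,
                                digits = NA, null = "null", na = "null"))
}

sha256_hex <- function(s) digest::digest(s, algo = "sha256", serialize = FALSE)

# ---- timestamps -------------------------------------------------------------

# timestamps are carried as fixed-width UTC ISO 8601 strings with millisecond
# precision ("2024-01-01T08:00:00.000Z"): fixed width makes lexicographic
# order equal temporal order, which the audit store relies on.
iso_to_ms <- function(s) {
  sec <- as.numeric(as.POSIXct(substr(s, 1, 19), format = "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC"))
  ms <- suppressWarnings(as.numeric(substr(s, 21, 23)))
  if (is.na(ms)) ms <- 0
  sec * 1000 + ms
}

ms_to_iso <- function(ms) {
  secs <- floor(ms / 1000)
  rem <- round(ms - secs * 1000)
  paste0(format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
                "%Y-%m-%dT%H:%M:%S"),
         sprintf(".%03dZ", as.integer(rem)))
}

ts_add_ms <- function(s, delta_ms) ms_to_iso(iso_to_ms(s) + delta_ms)

is_iso_ts <- function(s) {
  is.character(s) && length(s) == 1 && !is.na(s) &&
    grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}\\.\\d{3}Z$", s)
}

#' Wall-clock timestamp source
#'
#' A clock is a zero-argument function returning the current UTC time as an
#' ISO 8601 string with millisecond precision. The audit store takes its
#' timestamps from an injectable clock so that tests and reproducible exports
#' can run against [fixed_clock()].
#'
#' @return a clock function.
#' @export
system_clock <- function() {
  function() ms_to_iso(round(as.numeric(Sys.time()) * 1000))
}

#' Deterministic clock for reproducible runs
#'
#' Returns a clock that starts at `start` and advances by `step_ms`
#' milliseconds on every call.
#'
#' @param start ISO 8601 UTC start time.
#' @param step_ms increment per tick in milliseconds.
#' @return a clock function.
#' @export
fixed_clock <- function(start = "2024-01-01T08:00:00.000Z", step_ms = 1000) {
  stopifnot(is_iso_ts(start), step_ms >= 0)
  env <- new.env(parent = emptyenv())
  env$ms <- iso_to_ms(start) - step_ms
  function() {
    env$ms <- env$ms + step_ms
    ms_to_iso(env$ms)
  }
}

# ---- identifiers ------------------------------------------------------------

# RFC 4122 version-4 UUID drawn from the R random stream, so that fixture
# generation is fully reproducible under a seed while independently operated
# devices still never collide in practice.
uuid4 <- function() {
  b <- sample.int(256L, 16L, replace = TRUE) - 1L
  b[7] <- bitwOr(bitwAnd(b[7], 0x0FL), 0x40L)  # version 4
  b[9] <- bitwOr(bitwAnd(b[9], 0x3FL), 0x80L)  # RFC 4122 variant
  h <- sprintf("%02x", b)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

# ---- RFC 4180 CSV -----------------------------------------------------------

csv_escape_field <- function(x) {
  x <- enc2utf8(as.character(x))
  x[is.na(x)] <- ""
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

# RFC 4180 text for a data frame: UTF-8, LF line endings, header row, fields
# quoted only when necessary — fixed so that exports are byte-reproducible.
csv_text <- function(df) {
  header <- paste(csv_escape_field(names(df)), collapse = ",")
  if (nrow(df) == 0) return(paste0(header, "\n"))
  cols <- lapply(df, csv_escape_field)
  body <- do.call(paste, c(cols, sep = ","))
  paste0(header, "\n", paste(body, collapse = "\n"), "\n")
}

read_csv_strict <- function(path_or_text, text = FALSE) {
  if (text) {
    read.csv(text = path_or_text, colClasses = "character",
             check.names = FALSE, na.strings = character(0))
  } else {
    read.csv(path_or_text, colClasses = "character", check.names = FALSE,
             na.strings = character(0), fileEncoding = "UTF-8")
  }
}

blank_to_null <- function(x) if (is.null(x) || !nzchar(x)) NULL else x
null_to_blank <- function(x) if (is.null(x)) "" else as.character(x)

as_flag <- function(x) {
  if (is.logical(x) && length(x) == 1 && !is.na(x)) return(x)
  lx <- tolower(as.character(x))
  if (lx %in% c("true", "1")) TRUE
  else if (lx %in% c("false", "0")) FALSE
  else NA
}
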