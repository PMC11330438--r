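#' Create an append-only audit store
#'
#' The audit store is the single persistence primitive: every stored object
#' (participant registrations, per-visit value sets, metadata items) is a
#' chain of immutable versioned rows. Rows are never updated or removed;
#' edits append a new version and deletions append a row marked
#' `deleted = TRUE` that carries an unchanged copy of the payload it
#' deletes. Consequently the state of the database can be reconstructed for
#' any past time point ([query_as_of()]).
#'
#' Ordering authority is `(timestamp, row_seq)`. When an appended row's
#' clock reads earlier than its record's head (offline devices with skewed
#' clocks), the new timestamp is clamped to head + 1 ms and the event is
#' logged, keeping every chain monotone without rejecting field data.
#'
#' @param origin_id device/site token stamped on rows written here.
#' @param clock timestamp source, see [system_clock()] / [fixed_clock()].
#' @param study_id,metadata_version provenance recorded for merge
#'   compatibility checks.
#' @return an environment of class `edc_audit_store`.
#' @export
audit_store <- function(origin_id = "local", clock = system_clock(),
                        study_id = NULL, metadata_version = NULL) {
  store <- new.env(parent = emptyenv())
  store$rows <- vector("list", 64L)
  store$n <- 0L
  store$index <- new.env(parent = emptyenv())  # record_id -> integer row idxs
  store$read_only <- FALSE
  store$origin_id <- origin_id
  store$clock <- clock
  store$study_id <- study_id
  store$metadata_version <- metadata_version
  store$events <- list()
  class(store) <- "edc_audit_store"
  store
}

#' @export
print.edc_audit_store <- function(x, ...) {
  cat(sprintf("<audit store '%s': %d rows, %d records%s>\n", x$origin_id,
              x$n, length(ls(x$index)),
              if (x$read_only) ", read-only" else ""))
  invisible(x)
}

#' Number of rows in an audit store
#' @param store an `edc_audit_store`.
#' @export
store_size <- function(store) store$n

store_rows <- function(store) {
  if (store$n == 0) list() else store$rows[seq_len(store$n)]
}

log_store_event <- function(store, code, message) {
  store$events[[length(store$events) + 1L]] <-
    list(code = code, message = message, at = store$clock())
  invisible(store)
}

append_row_raw <- function(store, row) {
  if (store$n == length(store$rows)) {
    store$rows <- c(store$rows, vector("list", max(64L, store$n)))
  }
  store$n <- store$n + 1L
  row$row_seq <- store$n
  store$rows[[store$n]] <- row
  store$index[[row$record_id]] <- c(store$index[[row$record_id]], store$n)
  row
}

record_head <- function(store, record_id) {
  idx <- store$index[[record_id]]
  if (is.null(idx)) NULL else store$rows[[idx[length(idx)]]]
}

#' Append a new version of a record
#'
#' First write of a `record_id` creates version 1; subsequent writes append
#' version `head + 1`, superseding the current head. Prior rows are never
#' touched.
#'
#' @param store an `edc_audit_store`.
#' @param record_id stable identity of the logical record (a UUID).
#' @param payload named list; stored in canonical JSON form.
#' @param actor token of the acting user.
#' @param origin_id overrides the store's origin token.
#' @param entity one of `participant`, `visit_data`, `metadata_item`.
#' @return the appended row, invisibly.
#' @export
append_version <- function(store, record_id, payload, actor,
                           origin_id = store$origin_id,
                           entity = "visit_data") {
  if (store$read_only) {
    edc_error("STORE_READ_ONLY", "this store does not accept writes")
  }
  if (!entity %in% c("participant", "visit_data", "metadata_item")) {
    edc_error("BAD_ENTITY", sprintf("unknown entity '%s'", entity))
  }
  head <- record_head(store, record_id)
  ts <- store$clock()
  if (!is.null(head) && ts <= head$timestamp) {
    clamped <- ts_add_ms(head$timestamp, 1)
    log_store_event(store, "CLOCK_SKEW",
                    sprintf("timestamp %s for record %s clamped to %s",
                            ts, record_id, clamped))
    ts <- clamped
  }
  row <- list(
    row_seq = NA_integer_,
    record_id = record_id,
    entity = if (is.null(head)) entity else head$entity,
    payload = payload,
    payload_json = canonical_json(payload),
    version_no = if (is.null(head)) 1L else head$version_no + 1L,
    origin_id = origin_id,
    actor = actor,
    timestamp = ts,
    deleted = FALSE,
    supersedes = if (is.null(head)) NULL else
      list(record_id = record_id, version_no = head$version_no)
  )
  invisible(append_row_raw(store, row))
}

#' Soft-delete a record
#'
#' Appends a deletion row (with an unchanged copy of the head's payload);
#' the record disappears from [query_current()] but remains fully visible in
#' the audit trail and in [query_as_of()] before the deletion.
#'
#' @inheritParams append_version
#' @return the appended deletion row, invisibly.
#' @export
soft_delete <- function(store, record_id, actor,
                        origin_id = store$origin_id) {
  if (store$read_only) {
    edc_error("STORE_READ_ONLY", "this store does not accept writes")
  }
  head <- record_head(store, record_id)
  if (is.null(head)) {
    edc_error("UNKNOWN_RECORD", sprintf("no record '%s'", record_id))
  }
  if (head$deleted) {
    edc_error("ALREADY_DELETED", sprintf("record '%s' is already deleted", record_id))
  }
  ts <- store$clock()
  if (ts <= head$timestamp) {
    clamped <- ts_add_ms(head$timestamp, 1)
    log_store_event(store, "CLOCK_SKEW",
                    sprintf("timestamp %s for record %s clamped to %s",
                            ts, record_id, clamped))
    ts <- clamped
  }
  row <- list(
    row_seq = NA_integer_,
    record_id = record_id,
    entity = head$entity,
    payload = head$payload,
    payload_json = head$payload_json,
    version_no = head$version_no + 1L,
    origin_id = origin_id,
    actor = actor,
    timestamp = ts,
    deleted = TRUE,
    supersedes = list(record_id = record_id, version_no = head$version_no)
  )
  invisible(append_row_raw(store, row))
}

#' Current head records
#'
#' For each record, the maximum-version row; records whose head is a
#' deletion are excluded.
#'
#' @param store an `edc_audit_store`.
#' @param entity optional filter (`participant`, `visit_data`,
#'   `metadata_item`).
#' @return named list of rows, keyed and sorted by `record_id`.
#' @export
query_current <- function(store, entity = NULL) {
  ids <- sort(ls(store$index))
  out <- list()
  for (rid in ids) {
    head <- record_head(store, rid)
    if (head$deleted) next
    if (!is.null(entity) && head$entity != entity) next
    out[[rid]] <- head
  }
  out
}

#' Reconstruct the state of the store at a past time point
#'
#' For each record, the highest-version row with `timestamp <= t`; the
#' record is excluded if that row is a deletion. Pure function of
#' `(store, t)`: past snapshots never change as new rows are appended.
#'
#' @param store an `edc_audit_store`.
#' @param t UTC ISO 8601 timestamp string (millisecond precision).
#' @param entity optional entity filter.
#' @return named list of rows, keyed and sorted by `record_id`.
#' @export
query_as_of <- function(store, t, entity = NULL) {
  stopifnot(is_iso_ts(t))
  ids <- sort(ls(store$index))
  out <- list()
  for (rid in ids) {
    idx <- store$index[[rid]]
    best <- NULL
    for (i in idx) {  # chain timestamps are monotone: last match wins
      row <- store$rows[[i]]
      if (row$timestamp <= t) best <- row else break
    }
    if (is.null(best) || best$deleted) next
    if (!is.null(entity) && best$entity != entity) next
    out[[rid]] <- best
  }
  out
}

#' Full version history of one record
#'
#' @param store an `edc_audit_store`.
#' @param record_id record identity.
#' @return list of rows in version order, including deletion rows.
#' @export
history <- function(store, record_id) {
  idx <- store$index[[record_id]]
  if (is.null(idx)) {
    edc_error("UNKNOWN_RECORD", sprintf("no record '%s'", record_id))
  }
  store$rows[idx]
}

# ---- digests ----------------------------------------------------------------

row_digest_input <- function(row) {
  paste(row$row_seq, row$record_id, row$entity, row$version_no,
        row$origin_id, row$actor, row$timestamp, row$deleted,
        if (is.null(row$supersedes)) "" else
          paste0(row$supersedes$record_id, ":", row$supersedes$version_no),
        row$payload_json, sep = "\x1f")
}

#' Tamper-evidence digest over the store's rows
#'
#' SHA-256 over the canonical serialization of rows `1..upto`. Because rows
#' are append-only, the digest over any fixed prefix must never change; the
#' test suite asserts this after every operation.
#'
#' @param store an `edc_audit_store`.
#' @param upto digest the first `upto` rows (default: all).
#' @return a hex digest string.
#' @export
store_digest <- function(store, upto = store$n) {
  if (upto == 0) return(sha256_hex(""))
  lines <- vapply(store$rows[seq_len(upto)], row_digest_input, character(1))
  sha256_hex(paste(lines, collapse = "\n"))
}

payload_digest <- function(row) sha256_hex(row$payload_json)

# ---- tabular / CSV form -----------------------------------------------------

#' Audit log as a data frame
#'
#' One row per audit row with the payload JSON-encoded in a single column;
#' this is the `audit/audit_log.csv` layout of export bundles.
#'
#' @param store an `edc_audit_store`.
#' @return data frame with columns `row_seq`, `record_id`, `entity`,
#'   `version_no`, `origin_id`, `actor`, `timestamp`, `deleted`,
#'   `supersedes`, `payload_json`.
#' @export
audit_log_frame <- function(store) {
  rows <- store_rows(store)
  data.frame(
    row_seq = vapply(rows, function(r) r$row_seq, integer(1)),
    record_id = vapply(rows, function(r) r$record_id, character(1)),
    entity = vapply(rows, function(r) r$entity, character(1)),
    version_no = vapply(rows, function(r) r$version_no, integer(1)),
    origin_id = vapply(rows, function(r) r$origin_id, character(1)),
    actor = vapply(rows, function(r) r$actor, character(1)),
    timestamp = vapply(rows, function(r) r$timestamp, character(1)),
    deleted = vapply(rows, function(r) if (r$deleted) "true" else "false",
                     character(1)),
    supersedes = vapply(rows, function(r) {
      if (is.null(r$supersedes)) "" else
        paste0(r$supersedes$record_id, ":", r$supersedes$version_no)
    }, character(1)),
    payload_json = vapply(rows, function(r) r$payload_json, character(1)),
    stringsAsFactors = FALSE
  )
}

# rebuild a store from a list of finalized rows (merge, load); rows must
# already be in the desired order and get fresh row_seq values.
store_from_rows <- function(rows, origin_id = "merged", clock = system_clock(),
                            study_id = NULL, metadata_version = NULL) {
  store <- audit_store(origin_id = origin_id, clock = clock,
                       study_id = study_id,
                       metadata_version = metadata_version)
  for (row in rows) append_row_raw(store, row)
  store
}

row_from_log_record <- function(rec) {
  sup <- rec$supersedes
  list(
    row_seq = NA_integer_,
    record_id = rec$record_id,
    entity = rec$entity,
    payload = rec$payload,
    payload_json = rec$payload_json,
    version_no = as.integer(rec$version_no),
    origin_id = rec$origin_id,
    actor = rec$actor,
    timestamp = rec$timestamp,
    deleted = isTRUE(rec$deleted),
    supersedes = sup
  )
}
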