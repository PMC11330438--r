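# Merging the audit stores of independently operated offline devices.
#
# Rows are keyed by (record_id, version_no, origin_id). Devices generate
# record UUIDs locally, so independent devices are conflict-free by
# construction; conflicts can only arise when seeded/duplicated databases
# diverge on the same record version.

merge_key <- function(row) {
  paste(row$record_id, row$version_no, row$origin_id, sep = "\x1f")
}

# identical up to row_seq (which is store-local)
rows_equivalent <- function(a, b) {
  identical(a$payload_json, b$payload_json) &&
    identical(a$timestamp, b$timestamp) &&
    identical(a$actor, b$actor) &&
    identical(a$deleted, b$deleted) &&
    identical(a$entity, b$entity)
}

check_merge_sources <- function(sources) {
  stopifnot(length(sources) >= 1,
            all(vapply(sources, inherits, logical(1), "edc_audit_store")))
  sids <- unique(unlist(lapply(sources, function(s) s$study_id)))
  if (length(sids) > 1) {
    edc_error("METADATA_MISMATCH",
              sprintf("sources come from different studies: %s",
                      paste(sids, collapse = ", ")))
  }
  mvs <- unique(unlist(lapply(sources, function(s) s$metadata_version)))
  if (length(mvs) > 1) {
    edc_error("METADATA_MISMATCH",
              sprintf("sources have different metadata versions: %s",
                      paste(mvs, collapse = ", ")))
  }
  invisible(list(study_id = if (length(sids)) sids else NULL,
                 metadata_version = if (length(mvs)) mvs else NULL))
}

# group all source rows by merge key; returns list of groups, each a list of
# list(row, source) in source order
collect_groups <- function(sources) {
  groups <- new.env(parent = emptyenv())
  keys <- character(0)
  for (si in seq_along(sources)) {
    for (row in store_rows(sources[[si]])) {
      k <- merge_key(row)
      g <- groups[[k]]
      if (is.null(g)) keys <- c(keys, k)
      groups[[k]] <- c(g, list(list(row = row, source = si)))
    }
  }
  list(groups = groups, keys = keys)
}

group_conflict <- function(entries) {
  digests <- unique(vapply(entries, function(e) payload_digest(e$row),
                           character(1)))
  if (length(digests) <= 1) return(NULL)
  row <- entries[[1]]$row
  list(record_id = row$record_id,
       version_no = row$version_no,
       origin_ids = unique(vapply(entries, function(e) e$row$origin_id,
                                  character(1))),
       digests = sort(digests))
}

#' Detect merge conflicts without mutating anything
#'
#' Exactly the conflicts [merge_stores()] would raise under the strict
#' policy: merge keys `(record_id, version_no, origin_id)` that occur in
#' several sources with differing payload digests.
#'
#' @param sources list of `edc_audit_store` exported from the same study at
#'   the same metadata version (else `METADATA_MISMATCH`).
#' @return list of conflicts, each with `record_id`, `version_no`,
#'   `origin_ids`, `digests`.
#' @export
detect_conflicts <- function(sources) {
  check_merge_sources(sources)
  col <- collect_groups(sources)
  out <- list()
  for (k in col$keys) {
    cf <- group_conflict(col$groups[[k]])
    if (!is.null(cf)) out[[length(out) + 1L]] <- cf
  }
  out
}

#' Merge the audit stores of several offline devices
#'
#' Takes the union of audit rows over all sources, keyed by
#' `(record_id, version_no, origin_id)`. Byte-identical duplicates are
#' deduplicated. The same key with differing payload digests is a conflict:
#' under `strict` the merge aborts with `MERGE_CONFLICT` (report attached);
#' under `latest_wins` the row with the later `(timestamp, row_seq)` wins
#' and the loser is recorded in the report. Merged `row_seq` values are
#' reassigned in `(timestamp, record_id, version_no, origin_id)` order — a
#' fully content-determined order, so the strict-policy result is
#' independent of source ordering.
#'
#' @param sources list of `edc_audit_store` from the same study/metadata
#'   version.
#' @param policy `"strict"` (default) or `"latest_wins"`.
#' @return list with `store` (the merged `edc_audit_store`) and `report`
#'   (an `edc_merge_report`).
#' @export
merge_stores <- function(sources, policy = c("strict", "latest_wins")) {
  policy <- match.arg(policy)
  prov <- check_merge_sources(sources)
  col <- collect_groups(sources)

  rows_in <- vapply(sources, store_size, integer(1))
  names(rows_in) <- vapply(seq_along(sources), function(i) {
    sources[[i]]$origin_id %||% sprintf("source_%d", i)
  }, character(1))

  conflicts <- list()
  losers <- list()
  duplicates_skipped <- 0L
  kept <- list()

  for (k in col$keys) {
    entries <- col$groups[[k]]
    cf <- group_conflict(entries)
    if (is.null(cf)) {
      kept[[length(kept) + 1L]] <- entries[[1]]$row
      duplicates_skipped <- duplicates_skipped + length(entries) - 1L
    } else {
      conflicts[[length(conflicts) + 1L]] <- cf
      if (policy == "latest_wins") {
        ord <- order(vapply(entries, function(e) e$row$timestamp, character(1)),
                     vapply(entries, function(e) e$source, integer(1)),
                     vapply(entries, function(e) e$row$row_seq, integer(1)))
        winner <- entries[[ord[length(ord)]]]
        kept[[length(kept) + 1L]] <- winner$row
        for (e in entries[ord[-length(ord)]]) {
          losers[[length(losers) + 1L]] <-
            list(record_id = e$row$record_id, version_no = e$row$version_no,
                 origin_id = e$row$origin_id, digest = payload_digest(e$row))
        }
      }
    }
  }

  report <- structure(list(
    rows_in = rows_in,
    rows_out = NA_integer_,
    duplicates_skipped = duplicates_skipped,
    conflicts = conflicts,
    losers = losers,
    policy = policy,
    pid_remaps = list()
  ), class = "edc_merge_report")

  if (policy == "strict" && length(conflicts) > 0) {
    edc_error("MERGE_CONFLICT",
              sprintf("%d conflicting record version(s); merge aborted",
                      length(conflicts)),
              data = list(report = report))
  }

  ord <- order(vapply(kept, function(r) r$timestamp, character(1)),
               vapply(kept, function(r) r$record_id, character(1)),
               vapply(kept, function(r) r$version_no, integer(1)),
               vapply(kept, function(r) r$origin_id, character(1)))
  kept <- kept[ord]
  kept <- lapply(kept, function(r) { r$row_seq <- NA_integer_; r })

  kept <- remap_pid_collisions(kept, report)
  report <- attr(kept, "report")
  attr(kept, "report") <- NULL

  merged <- store_from_rows(kept, origin_id = "merged",
                            study_id = prov$study_id,
                            metadata_version = prov$metadata_version)
  report$rows_out <- store_size(merged)
  list(store = merged, report = report)
}

# Participants included on devices sharing a site prefix can collide on PID
# (e.g. both created "muc-0001" for different people). Colliding origins are
# remapped deterministically: origins are ranked lexicographically and every
# colliding origin after the first has its per-site sequence offset by
# rank * stride (stride: the next power of ten above the largest sequence
# seen, at least 10000). Remaps apply to the origin's participant rows and
# to the pid fields of its visit_data rows, and are listed in the report.
remap_pid_collisions <- function(rows, report) {
  part_rows <- Filter(function(r) r$entity == "participant", rows)
  if (length(part_rows) > 0) {
    pid_of <- vapply(part_rows, function(r) r$payload$pid, character(1))
    origin_of <- vapply(part_rows, function(r) r$origin_id, character(1))
    rid_of <- vapply(part_rows, function(r) r$record_id, character(1))
    # a collision: same pid used for different record_ids from different origins
    tab <- unique(data.frame(pid = pid_of, origin = origin_of, rid = rid_of,
                             stringsAsFactors = FALSE))
    dup_pids <- unique(tab$pid[duplicated(tab$pid)])
    dup_pids <- Filter(function(p) {
      length(unique(tab$rid[tab$pid == p])) > 1
    }, dup_pids)
    if (length(dup_pids) > 0) {
      seqs <- suppressWarnings(as.integer(sub("^.*-", "", pid_of)))
      stride <- max(10000L, 10L^ceiling(log10(max(seqs, na.rm = TRUE) + 1L)))
      origins <- sort(unique(origin_of))
      rank <- stats::setNames(seq_along(origins) - 1L, origins)
      remap <- list()  # origin -> (old pid -> new pid)
      for (p in dup_pids) {
        involved <- sort(unique(tab$origin[tab$pid == p]))
        for (oi in involved[-1]) {
          old_seq <- as.integer(sub("^.*-", "", p))
          site <- sub("-[0-9]+$", "", p)
          new_pid <- sprintf("%s-%04d", site, old_seq + rank[[oi]] * stride)
          if (is.null(remap[[oi]])) remap[[oi]] <- character(0)
          remap[[oi]][p] <- new_pid
          report$pid_remaps[[length(report$pid_remaps) + 1L]] <-
            list(origin_id = oi, old_pid = p, new_pid = new_pid)
        }
      }
      if (length(remap) > 0) {
        rows <- lapply(rows, function(r) {
          m <- remap[[r$origin_id]]
          if (!is.null(m) && !is.null(r$payload$pid) &&
              r$payload$pid %in% names(m)) {
            r$payload$pid <- unname(m[[r$payload$pid]])
            r$payload_json <- canonical_json(r$payload)
          }
          r
        })
      }
    }
  }
  attr(rows, "report") <- report
  rows
}

#' @export
print.edc_merge_report <- function(x, ...) {
  cat(sprintf("<merge report (%s): %s rows in, %d out, %d duplicates, %d conflict(s)%s>\n",
              x$policy, paste(x$rows_in, collapse = "+"),
              x$rows_out, x$duplicates_skipped, length(x$conflicts),
              if (length(x$pid_remaps) > 0)
                sprintf(", %d pid remap(s)", length(x$pid_remaps)) else ""))
  invisible(x)
}
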