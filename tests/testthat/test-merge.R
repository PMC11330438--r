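# helper: a deployed device store with its own origin and site
device_store <- function(origin, site, start, n_participants = 4,
                         seed = 1, study = tiny_study()) {
  withr::with_seed(seed, {
    state <- study_state(study, origin_id = origin,
                         clock = fixed_clock(start, 700))
    activate_deployment(state, "setup")
    for (i in seq_len(n_participants)) {
      p <- include_participant(state, site, "doc")
      submit_entry(state, p$pid, "baseline",
                   list(age = as.character(20 + i), sex = "f",
                        pregnant = "false", dx = "I10"), "doc")
    }
    state$store$metadata_version <- study$metadata_version
    state$store
  })
}

row_key_set <- function(store) {
  sort(vapply(edcforge:::store_rows(store), function(r) {
    paste(r$record_id, r$version_no, r$origin_id, r$payload_json, r$timestamp,
          sep = "|")
  }, character(1)))
}

# O(n^2) pairwise brute-force conflict finder, independent of the merge code
brute_force_conflicts <- function(stores) {
  rows <- unlist(lapply(stores, edcforge:::store_rows), recursive = FALSE)
  found <- character(0)
  for (i in seq_along(rows)) {
    for (j in seq_along(rows)) {
      if (i >= j) next
      a <- rows[[i]]; b <- rows[[j]]
      if (a$record_id == b$record_id && a$version_no == b$version_no &&
          a$origin_id == b$origin_id &&
          !identical(a$payload_json, b$payload_json)) {
        found <- c(found, paste(a$record_id, a$version_no))
      }
    }
  }
  sort(unique(found))
}

test_that("merging a single store is the identity on its rows", {
  a <- device_store("muc", "muc", "2024-01-01T08:00:00.000Z")
  res <- merge_stores(list(a))
  expect_identical(row_key_set(res$store), row_key_set(a))
  expect_identical(res$report$rows_out, store_size(a))
  expect_identical(res$report$duplicates_skipped, 0L)
})

test_that("strict merge is idempotent, commutative and associative", {
  a <- device_store("muc", "muc", "2024-01-01T08:00:00.000Z", seed = 1)
  b <- device_store("ber", "ber", "2024-01-01T08:30:00.000Z", seed = 2)
  c3 <- device_store("ham", "ham", "2024-01-01T09:00:00.000Z", seed = 3)

  # idempotence: duplicated inputs collapse
  expect_identical(row_key_set(merge_stores(list(a, a))$store), row_key_set(a))
  # commutativity: full result (including row_seq order) matches
  ab <- merge_stores(list(a, b))$store
  ba <- merge_stores(list(b, a))$store
  expect_identical(row_key_set(ab), row_key_set(ba))
  expect_identical(audit_log_frame(ab), audit_log_frame(ba))
  # associativity on the row sets
  abc1 <- merge_stores(list(merge_stores(list(a, b))$store, c3))$store
  abc2 <- merge_stores(list(a, merge_stores(list(b, c3))$store))$store
  abc3 <- merge_stores(list(a, b, c3))$store
  expect_identical(row_key_set(abc1), row_key_set(abc2))
  expect_identical(row_key_set(abc1), row_key_set(abc3))
  # audit preservation: every source row appears in the merged store
  expect_identical(row_key_set(abc3),
                   sort(c(row_key_set(a), row_key_set(b), row_key_set(c3))))
  # bookkeeping: rows_out = sum(rows_in) - duplicates_skipped
  res <- merge_stores(list(a, b, a))
  expect_identical(res$report$rows_out,
                   sum(res$report$rows_in) - res$report$duplicates_skipped)
})

test_that("time travel on the merged store covers each device's history", {
  a <- device_store("muc", "muc", "2024-01-01T08:00:00.000Z", seed = 1)
  b <- device_store("ber", "ber", "2024-01-01T12:00:00.000Z", seed = 2)
  merged <- merge_stores(list(a, b))$store
  t_mid <- "2024-01-01T09:00:00.000Z"  # after device A, before device B
  snap <- query_as_of(merged, t_mid)
  expect_identical(names(snap), names(query_as_of(a, t_mid)))
})

test_that("diverged copies of a seeded database conflict as detected by brute force", {
  study <- tiny_study()
  # one seeded store duplicated to two devices, which then edit the same
  # record version differently
  seedst <- device_store("seed", "muc", "2024-01-01T08:00:00.000Z",
                         n_participants = 2, study = study)
  rid <- edcforge:::store_rows(seedst)[[2]]$record_id
  clone <- function(origin, newval, start) {
    st <- edcforge:::store_from_rows(
      lapply(edcforge:::store_rows(seedst), function(r) r),
      origin_id = origin, clock = fixed_clock(start, 500),
      study_id = seedst$study_id, metadata_version = seedst$metadata_version)
    # both clones write version 2 of the same record under the seed origin
    head <- edcforge:::record_head(st, rid)
    row <- head
    row$version_no <- head$version_no + 1L
    row$payload$values$age <- newval
    row$payload_json <- edcforge:::canonical_json(row$payload)
    row$timestamp <- st$clock()
    row$supersedes <- list(record_id = rid, version_no = head$version_no)
    edcforge:::append_row_raw(st, row)
    st
  }
  d1 <- clone("seed", "77", "2024-01-02T08:00:00.000Z")
  d2 <- clone("seed", "88", "2024-01-02T09:00:00.000Z")

  conf <- detect_conflicts(list(d1, d2))
  expect_identical(length(conf), 1L)
  expect_identical(conf[[1]]$record_id, rid)
  expect_identical(paste(conf[[1]]$record_id, conf[[1]]$version_no),
                   brute_force_conflicts(list(d1, d2)))

  err <- expect_edc_error(merge_stores(list(d1, d2), policy = "strict"),
                          "MERGE_CONFLICT")
  expect_identical(length(err$data$report$conflicts), 1L)

  res <- merge_stores(list(d1, d2), policy = "latest_wins")
  merged_head <- query_current(res$store)[[rid]]
  expect_identical(merged_head$payload$values$age, "88")  # later timestamp won
  expect_identical(length(res$report$losers), 1L)

  # disjoint sites have no conflicts at all
  a <- device_store("muc", "muc", "2024-01-01T08:00:00.000Z", seed = 5)
  b <- device_store("ber", "ber", "2024-01-01T08:00:00.000Z", seed = 6)
  expect_identical(detect_conflicts(list(a, b)), list())
  expect_identical(brute_force_conflicts(list(a, b)), character(0))
})

test_that("sources from different studies or metadata versions are rejected", {
  a <- device_store("muc", "muc", "2024-01-01T08:00:00.000Z")
  other <- study_metadata("other_study",
                          visits = list(visit_definition("v1", order_index = 0L)))
  b_state <- study_state(other, origin_id = "ber")
  activate_deployment(b_state, "setup")
  expect_edc_error(merge_stores(list(a, b_state$store)), "METADATA_MISMATCH")

  c2 <- device_store("ber", "ber", "2024-01-01T08:00:00.000Z")
  c2$metadata_version <- 9L
  expect_edc_error(merge_stores(list(a, c2)), "METADATA_MISMATCH")
})

test_that("PID collisions across devices sharing a site are remapped", {
  a <- device_store("dev_a", "muc", "2024-01-01T08:00:00.000Z", seed = 7)
  b <- device_store("dev_b", "muc", "2024-01-01T10:00:00.000Z", seed = 8)
  res <- merge_stores(list(a, b))
  expect_true(length(res$report$pid_remaps) > 0)
  parts <- query_current(res$store, "participant")
  pids <- vapply(unname(parts), function(r) r$payload$pid, character(1))
  expect_identical(anyDuplicated(pids), 0L)
  # deterministic: the lexicographically later origin is offset
  remap <- res$report$pid_remaps[[1]]
  expect_identical(remap$origin_id, "dev_b")
  expect_match(remap$new_pid, "^muc-1000[0-9]$")
})
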