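day_records_store <- function() {
  # 5 records today, 3 yesterday, across two patients
  src <- dicom_store("rv", hierarchical_only = FALSE)
  uids_today <- sprintf("1.8.%d", 1:5)
  for (i in 1:5) {
    store_put(src, rec_fixture(uid = uids_today[i], date = "20240502",
                               fraction = i))
  }
  for (i in 6:8) {
    store_put(src, rec_fixture(uid = sprintf("1.8.%d", i), date = "20240501",
                               fraction = i))
  }
  list(src = src, uids_today = uids_today)
}

test_that("query_day_records filters by treatment date only and never duplicates", {
  f <- day_records_store()
  expect_setequal(query_day_records(f$src, as.Date("2024-05-02")), f$uids_today)
  expect_length(query_day_records(f$src, as.Date("2024-05-04")), 0L)
})

test_that("transfer_with_retry stops at first success and bounds attempts", {
  f <- day_records_store()
  dst <- dicom_store("pacs")

  res <- transfer_with_retry("1.8.1", f$src, dst)
  expect_equal(res$status, "SUCCESS")
  expect_equal(res$attempts, 1L)

  store_set_fault_policy(dst, fault_policy("FAIL_FIRST_K", k = 3))
  res <- transfer_with_retry("1.8.2", f$src, dst)
  expect_equal(res$status, "SUCCESS")
  expect_equal(res$attempts, 4L)

  store_set_fault_policy(dst, fault_policy("FAIL_ALWAYS"))
  res <- transfer_with_retry("1.8.3", f$src, dst, max_retries = 7L)
  expect_equal(res$status, "TRANSFER_FAILED")
  expect_equal(res$attempts, 8L) # 1 initial + 7 retries
})

test_that("journal persists per success and survives reopening", {
  dir <- withr::local_tempdir()
  j <- journal_open(dir, as.Date("2024-05-02"))
  journal_append(j, "1.8.1")
  journal_append(j, "1.8.2")
  journal_append(j, "1.8.1") # no-op
  expect_equal(journal_uids(j), c("1.8.1", "1.8.2"))
  # reopen: state reconstructed from the append-only file
  j2 <- journal_open(dir, as.Date("2024-05-02"))
  expect_equal(journal_uids(j2), c("1.8.1", "1.8.2"))
  # a new calendar date gets a fresh journal
  j3 <- journal_open(dir, as.Date("2024-05-03"))
  expect_length(journal_uids(j3), 0L)
})

test_that("failure log folds failed/resolved events across reopenings", {
  dir <- withr::local_tempdir()
  fl <- failure_log_open(dir)
  failure_log_record(fl, "1.8.9", attempts = 8L, last_status = "TRANSFER_FAILED")
  failure_log_record(fl, "1.8.10", attempts = 8L, last_status = "CONNECTION_FAILED")
  failure_log_resolve(fl, "1.8.10")
  fl2 <- failure_log_open(dir)
  entries <- failure_log_entries(fl2)
  expect_equal(entries$uid, "1.8.9")
  expect_equal(entries$attempts, 8L)
  first <- entries$first_failed_at
  failure_log_record(fl2, "1.8.9", attempts = 8L, last_status = "TRANSFER_FAILED")
  expect_equal(failure_log_entries(fl2)$first_failed_at, first)
})

test_that("run_cycle transfers only records absent from the day's journal", {
  f <- day_records_store()
  dst <- dicom_store("pacs")
  dir <- withr::local_tempdir()
  state <- backup_state(dir)
  now <- as.Date("2024-05-02")

  # pre-journal one of the five: exactly 4 move sequences expected
  state$journal <- journal_open(dir, now)
  journal_append(state$journal, "1.8.1")
  before <- f$src$n_move_out
  rep1 <- run_cycle(f$src, dst, state, now = now, closure = FALSE)
  expect_equal(f$src$n_move_out - before, 4L)
  expect_equal(rep1$n_queried, 5L)
  expect_equal(rep1$n_new, 4L)
  expect_equal(rep1$n_succeeded, 4L)
  expect_equal(nrow(rep1$failed), 0L)

  # second cycle: nothing new, zero transfers
  before <- f$src$n_move_out
  rep2 <- run_cycle(f$src, dst, state, now = now, closure = FALSE)
  expect_equal(f$src$n_move_out - before, 0L)
  expect_equal(rep2$n_new, 0L)
})

test_that("cycle report totals satisfy the conservation invariants", {
  f <- day_records_store()
  dst <- dicom_store("pacs")
  store_set_fault_policy(dst, fault_policy("FAIL_FIRST_K", k = 20)) # > budget
  state <- backup_state(withr::local_tempdir())
  now <- as.Date("2024-05-02")
  rep <- run_cycle(f$src, dst, state, now = now, closure = FALSE,
                   max_retries = 2L)
  expect_equal(rep$n_new, rep$n_succeeded + nrow(rep$failed))
  expect_lte(rep$n_new, rep$n_queried)
  # queried set splits disjointly between journal and failure log
  queried <- query_day_records(f$src, now)
  in_journal <- intersect(queried, journal_uids(state$journal))
  in_flog <- intersect(queried, failure_log_entries(state$failure_log)$uid)
  expect_length(intersect(in_journal, in_flog), 0L)
  expect_setequal(c(in_journal, in_flog), queried)
})

test_that("a record failed in one cycle leaves the failure log after later success", {
  f <- day_records_store()
  dst <- dicom_store("pacs")
  state <- backup_state(withr::local_tempdir())
  now <- as.Date("2024-05-02")

  store_set_fault_policy(dst, fault_policy("FAIL_ALWAYS"))
  rep1 <- run_cycle(f$src, dst, state, now = now, closure = FALSE)
  expect_equal(nrow(rep1$failed), 5L)
  expect_equal(unique(rep1$failed$attempts), 8L)
  expect_setequal(failure_log_entries(state$failure_log)$uid, f$uids_today)

  store_set_fault_policy(dst, fault_policy("NONE"))
  rep2 <- run_cycle(f$src, dst, state, now = now, closure = FALSE)
  expect_equal(rep2$n_succeeded, 5L)
  expect_equal(nrow(failure_log_entries(state$failure_log)), 0L)
  expect_setequal(journal_uids(state$journal), f$uids_today)
})

test_that("source connection failure aborts the cycle with an error-flagged report", {
  f <- day_records_store()
  dst <- dicom_store("pacs")
  state <- backup_state(withr::local_tempdir())
  store_set_connection(f$src, down = TRUE)
  rep <- run_cycle(f$src, dst, state, now = as.Date("2024-05-02"))
  expect_equal(rep$n_queried, 0L)
  expect_false(is.null(rep$error))
})

test_that("a wholly-down destination sends all new records to the failure log as CONNECTION_FAILED", {
  f <- day_records_store()
  dst <- dicom_store("pacs")
  store_set_fault_policy(dst, fault_policy("CONNECTION_DOWN"))
  state <- backup_state(withr::local_tempdir())
  rep <- run_cycle(f$src, dst, state, now = as.Date("2024-05-02"),
                   closure = FALSE)
  expect_equal(rep$n_succeeded, 0L)
  expect_equal(unique(rep$failed$last_status), "CONNECTION_FAILED")
  expect_equal(unique(failure_log_entries(state$failure_log)$last_status),
               "CONNECTION_FAILED")
})

test_that("interrupted days complete on re-run with no record transferred twice", {
  f <- day_records_store()
  dst <- dicom_store("pacs")
  dir <- withr::local_tempdir()
  now <- as.Date("2024-05-02")

  # first process archives two of five, journalling each, then "crashes"
  state1 <- backup_state(dir)
  state1$journal <- journal_open(dir, now)
  for (uid in c("1.8.1", "1.8.2")) {
    transfer_with_retry(uid, f$src, dst)
    journal_append(state1$journal, uid)
  }

  # second process picks up the persisted journal and finishes the day
  state2 <- backup_state(dir)
  rep <- run_cycle(f$src, dst, state2, now = now, closure = FALSE)
  expect_equal(rep$n_new, 3L)
  expect_true(all(dst$success_moves == 1L))
  expect_setequal(journal_uids(state2$journal), f$uids_today)
})

test_that("cross-midnight duplicates are blocked by the destination-existence check", {
  f <- day_records_store()
  dst <- dicom_store("pacs")
  dir <- withr::local_tempdir()
  now <- as.Date("2024-05-02")
  # record archived under *yesterday's* journal (journal for today is empty)
  transfer_with_retry("1.8.1", f$src, dst)
  state <- backup_state(dir)
  rep <- run_cycle(f$src, dst, state, now = now, closure = FALSE)
  expect_equal(rep$n_succeeded, 5L)
  expect_equal(dst$success_moves[["1.8.1"]], 1L) # not moved again
})

test_that("daily report aggregates cycles and flags a cycle-free day", {
  f <- day_records_store()
  dst <- dicom_store("pacs")
  dir <- withr::local_tempdir()
  state <- backup_state(dir)
  now <- as.Date("2024-05-02")
  r1 <- run_cycle(f$src, dst, state, now = now, closure = FALSE)
  r2 <- run_cycle(f$src, dst, state, now = now, closure = FALSE)

  out <- withr::local_tempdir()
  summary <- emit_daily_report(list(r1, r2), dir = out)
  expect_equal(summary$n_succeeded, 5L)
  expect_equal(summary$n_cycles, 2L)
  expect_false(summary$no_cycles)
  expect_true(file.exists(file.path(out, "report-20240502.txt")))
  json <- jsonlite::read_json(file.path(out, "report-20240502.json"))
  expect_equal(json$n_succeeded, 5L)

  # rebuilt from persisted per-cycle state, same numbers
  from_state <- emit_daily_report(dir, date = now, dir = out)
  expect_equal(from_state$n_succeeded, 5L)

  none <- emit_daily_report(list(), date = as.Date("2024-05-03"), dir = out)
  expect_true(none$no_cycles)
  expect_match(none$text, "non-operational")

  # a failed uid is listed with attempts and final status
  dst2 <- dicom_store("pacs2")
  store_set_fault_policy(dst2, fault_policy("FAIL_ALWAYS"))
  f2 <- day_records_store()
  st2 <- backup_state(withr::local_tempdir())
  rf <- run_cycle(f2$src, dst2, st2, now = now, closure = FALSE)
  sf <- emit_daily_report(list(rf), dir = out)
  expect_equal(nrow(sf$failures), 5L)
  expect_match(sf$text, "attempts=8")

  # cycles from different dates are rejected
  r_other <- run_cycle(f$src, dst, state, now = as.Date("2024-05-03"),
                       closure = FALSE)
  expect_error(emit_daily_report(list(r1, r_other)), class = "rt_report_error")
})
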