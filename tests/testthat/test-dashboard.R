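test_that("calendar-month subtraction clamps the day of month", {
  expect_equal(months_before(as.Date("2024-03-31"), 2), as.Date("2024-01-31"))
  expect_equal(months_before(as.Date("2024-05-31"), 3), as.Date("2024-02-29"))
  expect_equal(months_before(as.Date("2023-05-31"), 3), as.Date("2023-02-28"))
  expect_equal(months_before(as.Date("2024-01-15"), 2), as.Date("2023-11-15"))
  expect_equal(months_before(as.Date("2024-06-28"), 0), as.Date("2024-06-28"))
})

# One archive, several studies at controlled month offsets, one record each.
offset_archive <- function(reference_date, offsets_days) {
  archive <- dicom_store("pacs")
  uids <- character(length(offsets_days))
  for (i in seq_along(offsets_days)) {
    sd <- da_format(reference_date - offsets_days[i])
    uid <- sprintf("1.6.%d", i)
    pid <- sprintf("ZZ%06d", i)
    store_put(archive, rec_fixture(
      uid = uid, plan_uid = sprintf("1.6.%d.5", i), date = sd,
      patient_id = pid, patient_name = sprintf("ZZTEST^P%03d", i),
      study_uid = sprintf("1.6.%d.100", i),
      series_uid = sprintf("1.6.%d.101", i), study_date = sd
    ))
    uids[i] <- uid
  }
  list(archive = archive, uids = uids)
}

test_that("candidate query admits studies up to exactly two calendar months back", {
  ref <- as.Date("2024-06-28")
  # offsets approximating 1..6 months
  offsets <- c(30, 59, 91, 122, 152, 183)
  f <- offset_archive(ref, offsets)
  got <- query_candidate_records(f$archive, ref)
  window_start <- months_before(ref, 2) # 2024-04-28, i.e. 61 days before
  expect_setequal(got$instance_uid, f$uids[offsets <= 61])

  # boundary: exactly the window edge is admitted, one day older is not
  edge <- offset_archive(ref, as.integer(ref - window_start) + c(0L, 1L))
  got_edge <- query_candidate_records(edge$archive, ref)
  expect_equal(got_edge$instance_uid, edge$uids[1])

  empty <- dicom_store("empty")
  expect_equal(nrow(query_candidate_records(empty, ref)), 0L)
})

test_that("candidate query equals a brute-force scan filtered by study date", {
  clinic <- generate_clinic(clinic_spec(n_patients = 6, seed = 4))
  ref <- clinic$current_date
  got <- query_candidate_records(clinic$archive, ref)
  inst <- store_instances(clinic$archive)
  recs <- inst[inst$sop_class == rt_sop_classes$TREATMENT_RECORD, ]
  sd <- da_parse(recs$study_date, "StudyDate")
  want <- recs$instance_uid[sd >= months_before(ref, 2) & sd <= ref]
  expect_setequal(got$instance_uid, want)
})

roster_case <- function(fraction, fractions_planned, last_days_ago,
                        ref = as.Date("2024-06-28")) {
  archive <- dicom_store("pacs")
  sd <- da_format(ref - 30)
  store_put(archive, rec_fixture(uid = "1.6.1", plan_uid = "1.6.5",
                                 date = da_format(ref - last_days_ago),
                                 fraction = fraction, study_date = sd))
  store_put(archive, plan_fixture(uid = "1.6.5", fractions = fractions_planned,
                                  study_date = sd, series_uid = "1.6.102",
                                  struct_uid = NULL))
  build_dashboard(archive, ref)
}

test_that("course completion and the seven-day recency window gate the roster", {
  # fraction 25 of 25 delivered yesterday: course complete, excluded
  expect_equal(nrow(roster_case(25L, 25L, 1L)), 0L)
  # mid-course, last fractions 6/7/8 days ago: in, in (inclusive boundary), out
  expect_equal(nrow(roster_case(10L, 25L, 6L)), 1L)
  expect_equal(nrow(roster_case(10L, 25L, 7L)), 1L)
  expect_equal(nrow(roster_case(10L, 25L, 8L)), 0L)
})

test_that("per (patient, plan) only the most recent record survives", {
  ref <- as.Date("2024-06-28")
  archive <- dicom_store("pacs")
  sd <- da_format(ref - 30)
  store_put(archive, rec_fixture(uid = "1.6.1", plan_uid = "1.6.5",
                                 date = da_format(ref - 2), fraction = 11L,
                                 study_date = sd))
  store_put(archive, rec_fixture(uid = "1.6.2", plan_uid = "1.6.5",
                                 date = da_format(ref - 1), fraction = 12L,
                                 study_date = sd))
  store_put(archive, plan_fixture(uid = "1.6.5", fractions = 25L,
                                  study_date = sd, series_uid = "1.6.102",
                                  struct_uid = NULL))
  rows <- build_dashboard(archive, ref)
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$current_fraction, 12L)
  expect_equal(rows$last_treatment_date, ref - 1)

  # same date, later time wins
  store_put(archive, rec_fixture(uid = "1.6.3", plan_uid = "1.6.5",
                                 date = da_format(ref - 1), fraction = 13L,
                                 time = "235900", study_date = sd))
  expect_equal(build_dashboard(archive, ref)$current_fraction, 13L)
})

test_that("a record whose plan is missing keeps its row, flagged, with a warning", {
  ref <- as.Date("2024-06-28")
  archive <- dicom_store("pacs")
  store_put(archive, rec_fixture(uid = "1.6.1", plan_uid = "1.6.5",
                                 date = da_format(ref - 1), fraction = 3L,
                                 study_date = da_format(ref - 20)))
  expect_warning(rows <- build_dashboard(archive, ref),
                 class = "rt_dashboard_warning")
  expect_equal(nrow(rows), 1L)
  expect_true(is.na(rows$fractions_planned))
})

test_that("roster matches the ledger-derived brute force on random clinics", {
  for (seed in 0:4) {
    clinic <- generate_clinic(clinic_spec(n_patients = 8, seed = seed))
    ref <- clinic$current_date
    got <- build_dashboard(clinic$archive, ref)
    want <- roster_from_ledger(clinic$ledger, ref)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("enlarging the recency window never removes roster rows", {
  clinic <- generate_clinic(clinic_spec(n_patients = 10, seed = 6))
  ref <- clinic$current_date
  records <- query_candidate_records(clinic$archive, ref)
  lookup <- store_plan_lookup(clinic$archive)
  narrow <- select_current(records, ref, lookup, recency_days = 7L)
  wide <- select_current(records, ref, lookup, recency_days = 14L)
  key <- function(x) paste(x$mrn, x$plan_label)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("dashboard CSV has the exact contract header, ISO dates, and round-trips", {
  clinic <- generate_clinic(clinic_spec(n_patients = 8, seed = 7))
  rows <- build_dashboard(clinic$archive, clinic$current_date)
  expect_gt(nrow(rows), 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dashboard(rows, path)

  lines <- readLines(path)
  expect_equal(
    lines[1],
    "PatientName,MRN,DOB,Physician,PlanLabel,FractionsPlanned,CurrentFraction,LastTreatmentDate"
  )
  expect_match(lines[2], ",\\d{4}-\\d{2}-\\d{2}$") # ISO last-treatment date
  expect_equal(read_dashboard(path), rows)

  # zero rows: header-only file
  empty <- rows[0, ]
  write_dashboard(empty, path)
  expect_length(readLines(path), 1L)

  # determinism: identical archive and date give byte-identical output
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dashboard(build_dashboard(clinic$archive, clinic$current_date), path2)
  expect_identical(readLines(path2), lines)
})

test_that("roster rows for one patient are contiguous and ordered", {
  clinic <- generate_clinic(clinic_spec(n_patients = 12, seed = 8))
  rows <- build_dashboard(clinic$archive, clinic$current_date)
  runs <- rle(rows$mrn)$values
  expect_false(any(duplicated(runs))) # each patient appears in one block
  expect_equal(rows$patient_name, sort(rows$patient_name))
})
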