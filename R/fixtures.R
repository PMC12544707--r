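# Synthetic clinics are generated under a reserved test UID root so no
# generated identifier can collide with a real clinical UID, and all patient
# identities use an obviously synthetic scheme (ZZTEST^Pnnn) — the standard
# safety convention for anything DICOM-shaped.
.test_uid_root <- "1.2.826.0.1.3680043.10.474"

.physician_pool <- c("ADAMS^A", "BAKER^B", "CHEN^C", "DIAZ^D", "EVANS^E")

#' Specification of a synthetic radiotherapy clinic
#'
#' Describes the population a [generate_clinic()] call emulates: how many
#' patients, how many plans (courses) each carries, the range of fractionation
#' schedules, when courses start, which weekdays treatments are delivered,
#' and — to emulate the imperfect manual archiving the closure audit exists
#' for — the per-object-kind probability that an object is omitted from the
#' archive despite existing at the source. The same spec and seed always
#' produce identical stores and ledger.
#'
#' @param n_patients Number of patients (>= 1).
#' @param plans_per_patient Length-1 or -2 integer vector: fixed count or
#'   inclusive range of treatment plans per patient.
#' @param fractions_range Inclusive integer range of fractions planned per
#'   course (min >= 1).
#' @param as_of Simulation "today": fractions dated after this are not yet
#'   delivered at generation time.
#' @param start_date_window Length-2 `Date` vector from which course start
#'   dates are drawn; defaults to the 10 weeks up to `as_of`.
#' @param treatment_days Integer weekdays treatments are delivered
#'   (1 = Monday ... 7 = Sunday); default Monday-Friday.
#' @param gap_rates Named list of omission probabilities for `PLAN`,
#'   `STRUCTURE_SET`, `CT_SERIES`, `TREATMENT_RECORD`; unnamed kinds default
#'   to 0.
#' @param seed Integer seed; together with the other fields it fully
#'   determines the generated clinic.
#' @return A validated `rt_clinic_spec` list.
#' @export
clinic_spec <- function(n_patients = 20L,
                        plans_per_patient = c(1L, 2L),
                        fractions_range = c(5L, 35L),
                        as_of = as.Date("2024-06-28"),
                        start_date_window = NULL,
                        treatment_days = 1:5,
                        gap_rates = list(),
                        seed = 0L) {
  as_of <- as.Date(as_of)
  if (is.null(start_date_window)) start_date_window <- c(as_of - 70L, as_of)
  start_date_window <- as.Date(start_date_window)
  bad <- function(msg) rt_abort("rt_spec_error", msg)
  if (n_patients < 1L) bad("n_patients must be >= 1")
  if (length(plans_per_patient) < 1L || any(plans_per_patient < 1L)) {
    bad("plans_per_patient must be a positive count or range")
  }
  if (length(fractions_range) != 2L || fractions_range[1L] < 1L ||
      fractions_range[2L] < fractions_range[1L]) {
    bad("fractions_range must be an increasing pair with min >= 1")
  }
  treatment_days <- sort(unique(as.integer(treatment_days)))
  if (length(treatment_days) == 0L || any(!treatment_days %in% 1:7)) {
    bad("treatment_days must be a non-empty subset of 1..7 (Mon..Sun)")
  }
  rates <- list(PLAN = 0, STRUCTURE_SET = 0, CT_SERIES = 0,
                TREATMENT_RECORD = 0)
  for (k in names(gap_rates)) {
    if (!k %in% names(rates)) bad(sprintf("unknown gap_rates kind: %s", k))
    p <- gap_rates[[k]]
    if (!is.numeric(p) || p < 0 || p > 1) {
      bad(sprintf("gap rate for %s must be in [0, 1]", k))
    }
    rates[[k]] <- p
  }
  if (start_date_window[2L] < start_date_window[1L]) {
    bad("start_date_window must be an increasing date pair")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         plans_per_patient = as.integer(plans_per_patient),
         fractions_range = as.integer(fractions_range),
         as_of = as_of, start_date_window = start_date_window,
         treatment_days = treatment_days, gap_rates = rates,
         seed = as.integer(seed)),
    class = "rt_clinic_spec"
  )
}

weekday_of <- function(d) as.integer(format(as.Date(d), "%u"))

# sample() treats a scalar as 1:n; ranges here must not
sample_range <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1L)

# The full delivery calendar of a course: the first `n` dates on treatment
# weekdays starting at (or after) `start`.
treatment_schedule <- function(start, n, treatment_days) {
  days <- seq(as.Date(start), by = "1 day",
              length.out = ceiling(n * 7 / length(treatment_days)) + 7L)
  days[weekday_of(days) %in% treatment_days][seq_len(n)]
}

new_uid_fun <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  function() {
    env$n <- env$n + 1L
    sprintf("%s.%d.%d", .test_uid_root, seed, env$n)
  }
}

#' Generate a synthetic clinic: source store, archive store, ledger
#'
#' Builds the complete linked object chains — planning CT series, structure
#' set, plan, and one treatment record per already-delivered fraction — for
#' every course in the spec, places them in a relaxed-query source store
#' (the record-and-verify stand-in) and mirrors them into a
#' hierarchical-only archive store minus any objects flagged for omission by
#' `gap_rates`. Study dates are the simulation-CT creation dates, a few days
#' before each course starts. The returned ground-truth ledger exactly
#' describes what was generated, so every pipeline output can be checked
#' against a ledger-derived brute force that shares no code with the
#' pipeline.
#'
#' @param spec A [clinic_spec()].
#' @return An `rt_clinic` environment with fields `source`, `archive`,
#'   `ledger` (list of tibbles `patients`, `courses`, `records`, plus the
#'   spec), `current_date` (= `spec$as_of`) and the UID generator.
#' @export
generate_clinic <- function(spec) {
  stopifnot(inherits(spec, "rt_clinic_spec"))
  set.seed(spec$seed)
  new_uid <- new_uid_fun(spec$seed)

  source <- dicom_store("rv-source", hierarchical_only = FALSE)
  archive <- dicom_store("rt-pacs", hierarchical_only = TRUE)

  patients <- list()
  courses <- list()
  records <- list()

  ppp <- spec$plans_per_patient
  win <- spec$start_date_window
  for (i in seq_len(spec$n_patients)) {
    mrn <- sprintf("ZZ%06d", 100000L + i)
    name <- sprintf("ZZTEST^P%03d", i)
    dob <- as.Date("1940-01-01") + sample.int(18263L, 1L) - 1L
    physician <- sample(.physician_pool, 1L)
    tx_time <- sprintf("%02d%02d00", 7L + (i %% 10L), 15L * (i %% 4L))
    patients[[i]] <- tibble::tibble(
      patient_id = mrn, patient_name = name, birth_date = dob,
      physician = physician
    )
    n_plans <- if (length(ppp) == 1L) ppp else sample_range(ppp[1L], ppp[2L])

    for (j in seq_len(n_plans)) {
      start <- win[1L] + sample.int(as.integer(win[2L] - win[1L]) + 1L, 1L) - 1L
      while (!weekday_of(start) %in% spec$treatment_days) start <- start + 1L
      n_frac <- sample_range(spec$fractions_range[1L], spec$fractions_range[2L])
      schedule <- treatment_schedule(start, n_frac, spec$treatment_days)
      study_date <- start - sample_range(3L, 10L)

      study_uid <- new_uid(); ct_series <- new_uid()
      ct_insts <- c(new_uid(), new_uid())
      struct_series <- new_uid(); struct_uid <- new_uid()
      plan_series <- new_uid(); plan_uid <- new_uid()
      record_series <- new_uid()
      plan_label <- sprintf("%s_PLAN%d", mrn, j)

      common <- list(PatientID = mrn, PatientName = name,
                     PatientBirthDate = da_format(dob),
                     StudyInstanceUID = study_uid,
                     StudyDate = da_format(study_date),
                     PhysiciansOfRecord = physician)
      ct_attrs <- lapply(seq_along(ct_insts), function(k) {
        c(common, list(SeriesInstanceUID = ct_series, Modality = "CT",
                       SOPClassUID = rt_sop_classes$CT_IMAGE,
                       SOPInstanceUID = ct_insts[k], InstanceNumber = k))
      })
      struct_attrs <- c(common, list(
        SeriesInstanceUID = struct_series, Modality = "RTSTRUCT",
        SOPClassUID = rt_sop_classes$STRUCTURE_SET,
        SOPInstanceUID = struct_uid,
        ReferencedFrameOfReferenceSequence = list(list(
          RTReferencedStudySequence = list(list(
            RTReferencedSeriesSequence = list(list(
              SeriesInstanceUID = ct_series))))))
      ))
      plan_attrs <- c(common, list(
        SeriesInstanceUID = plan_series, Modality = "RTPLAN",
        SOPClassUID = rt_sop_classes$PLAN,
        SOPInstanceUID = plan_uid, RTPlanLabel = plan_label,
        FractionGroupSequence = list(list(NumberOfFractionsPlanned = n_frac)),
        ReferencedStructureSetSequence = list(list(
          ReferencedSOPInstanceUID = struct_uid))
      ))

      for (a in ct_attrs) store_put(source, a)
      store_put(source, struct_attrs)
      store_put(source, plan_attrs)

      gaps <- spec$gap_rates
      ct_in_archive <- stats::runif(1L) >= gaps$CT_SERIES
      struct_in_archive <- stats::runif(1L) >= gaps$STRUCTURE_SET
      plan_in_archive <- stats::runif(1L) >= gaps$PLAN
      if (ct_in_archive) for (a in ct_attrs) store_put(archive, a)
      if (struct_in_archive) store_put(archive, struct_attrs)
      if (plan_in_archive) store_put(archive, plan_attrs)

      courses[[length(courses) + 1L]] <- tibble::tibble(
        patient_id = mrn, patient_name = name, birth_date = dob,
        physician = physician, plan_uid = plan_uid, plan_label = plan_label,
        struct_uid = struct_uid, ct_series_uid = ct_series,
        study_uid = study_uid, record_series_uid = record_series,
        study_date = study_date, start_date = start,
        fractions_planned = n_frac, treatment_time = tx_time,
        schedule = list(schedule),
        plan_in_archive = plan_in_archive,
        struct_in_archive = struct_in_archive,
        ct_in_archive = ct_in_archive
      )

      delivered <- schedule[schedule <= spec$as_of]
      for (k in seq_along(delivered)) {
        rec_uid <- new_uid()
        rec_attrs <- record_attrs(courses[[length(courses)]], k,
                                  delivered[k], rec_uid)
        store_put(source, rec_attrs)
        rec_in_archive <- stats::runif(1L) >= gaps$TREATMENT_RECORD
        if (rec_in_archive) store_put(archive, rec_attrs)
        records[[length(records) + 1L]] <- tibble::tibble(
          record_uid = rec_uid, patient_id = mrn, plan_uid = plan_uid,
          fraction = k, date = delivered[k], time = tx_time,
          in_archive = rec_in_archive
        )
      }
    }
  }

  empty_records <- tibble::tibble(
    record_uid = character(), patient_id = character(),
    plan_uid = character(), fraction = integer(),
    date = as.Date(character()), time = character(), in_archive = logical()
  )
  clinic <- new.env(parent = emptyenv())
  clinic$source <- source
  clinic$archive <- archive
  clinic$ledger <- list(
    spec = spec,
    patients = dplyr::bind_rows(patients),
    courses = dplyr::bind_rows(courses),
    records = if (length(records)) dplyr::bind_rows(records) else empty_records
  )
  clinic$current_date <- spec$as_of
  clinic$new_uid <- new_uid
  class(clinic) <- "rt_clinic"
  clinic
}

record_attrs <- function(course, fraction, date, rec_uid) {
  list(
    PatientID = course$patient_id, PatientName = course$patient_name,
    PatientBirthDate = da_format(course$birth_date),
    PhysiciansOfRecord = course$physician,
    StudyInstanceUID = course$study_uid,
    StudyDate = da_format(course$study_date),
    SeriesInstanceUID = course$record_series_uid, Modality = "RTRECORD",
    SOPClassUID = rt_sop_classes$TREATMENT_RECORD,
    SOPInstanceUID = rec_uid,
    TreatmentDate = da_format(date), TreatmentTime = course$treatment_time,
    ReferencedRTPlanSequence = list(list(
      ReferencedSOPInstanceUID = course$plan_uid)),
    TreatmentSessionBeamSequence = list(
      list(CurrentFractionNumber = fraction),
      list(CurrentFractionNumber = fraction)
    )
  )
}

#' @export
print.rt_clinic <- function(x, ...) {
  cat(sprintf(
    "<rt_clinic as of %s> %d patients, %d courses, %d delivered fractions\n",
    x$current_date, nrow(x$ledger$patients), nrow(x$ledger$courses),
    nrow(x$ledger$records)
  ))
  invisible(x)
}

#' Advance the simulated clinic by one day
#'
#' Appends to the source store (and the ledger) one new treatment record for
#' every course scheduled to treat on `date`; the archive is untouched —
#' propagating new records there is the backup engine's job. Days outside a
#' course's schedule (weekends, completed courses) contribute nothing.
#'
#' @param clinic An `rt_clinic` from [generate_clinic()].
#' @param date The day to simulate; must be later than the clinic's current
#'   date.
#' @return The clinic, invisibly (modified in place).
#' @export
advance_day <- function(clinic, date) {
  date <- as.Date(date)
  if (date <= clinic$current_date) {
    rt_abort("rt_spec_error",
             sprintf("advance_day date %s is not after current date %s",
                     date, clinic$current_date))
  }
  courses <- clinic$ledger$courses
  new_rows <- list()
  for (i in seq_len(nrow(courses))) {
    course <- courses[i, ]
    sched <- course$schedule[[1L]]
    k <- match(date, sched)
    if (is.na(k)) next
    rec_uid <- clinic$new_uid()
    store_put(clinic$source, record_attrs(course, k, date, rec_uid))
    new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
      record_uid = rec_uid, patient_id = course$patient_id,
      plan_uid = course$plan_uid, fraction = k, date = date,
      time = course$treatment_time, in_archive = FALSE
    )
  }
  if (length(new_rows)) {
    clinic$ledger$records <- dplyr::bind_rows(clinic$ledger$records,
                                              dplyr::bind_rows(new_rows))
  }
  clinic$current_date <- date
  invisible(clinic)
}

#' Ledger-derived brute-force on-treatment roster
#'
#' Computes who is currently being treated straight from the ground-truth
#' ledger — no store queries, no pipeline code: per course, the delivered
#' fractions up to `reference_date` give the current fraction and last
#' treatment date; a course is on the roster when its study date falls in
#' the lookback window, it is not complete, and its last fraction is within
#' the recency window (inclusive). This is the independent oracle the
#' dashboard pipeline is compared against.
#'
#' @param ledger Ledger list from an `rt_clinic`.
#' @param reference_date Roster date.
#' @param recency_days,lookback_months Window parameters, as in
#'   [select_current()] / [query_candidate_records()].
#' @return Tibble with the same columns and ordering as [select_current()].
#' @export
roster_from_ledger <- function(ledger, reference_date, recency_days = 7L,
                               lookback_months = 2L) {
  reference_date <- as.Date(reference_date)
  window_start <- months_before(reference_date, lookback_months)
  out <- list()
  for (i in seq_len(nrow(ledger$courses))) {
    course <- ledger$courses[i, ]
    if (course$study_date < window_start || course$study_date > reference_date) next
    recs <- ledger$records[ledger$records$plan_uid == course$plan_uid &
                             ledger$records$date <= reference_date, ]
    if (nrow(recs) == 0L) next
    current <- max(recs$fraction)
    last_date <- max(recs$date)
    if (current >= course$fractions_planned) next
    if (as.numeric(reference_date - last_date) > recency_days) next
    out[[length(out) + 1L]] <- tibble::tibble(
      patient_name = course$patient_name, mrn = course$patient_id,
      dob = course$birth_date, physician = course$physician,
      plan_label = course$plan_label,
      fractions_planned = course$fractions_planned,
      current_fraction = as.integer(current),
      last_treatment_date = last_date
    )
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      patient_name = character(), mrn = character(),
      dob = as.Date(character()), physician = character(),
      plan_label = character(), fractions_planned = integer(),
      current_fraction = integer(), last_treatment_date = as.Date(character())
    ))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$patient_name, .data$mrn, .data$plan_label)
}

#' Drive the backup engine over a span of simulated days
#'
#' For each day after the clinic's current date: simulate the day's
#' treatments ([advance_day()]) and run `cycles_per_day` backup cycles
#' against the clinic's archive. The multi-day conservation and
#' fault-recovery properties are measured on the end state this produces.
#'
#' @param clinic An `rt_clinic`.
#' @param n_days Number of consecutive days to simulate.
#' @param state_dir Engine state directory (journal, failure log, cycle
#'   summaries).
#' @param max_retries Per-record retry budget.
#' @param cycles_per_day Backup cycles per simulated day (default 2, so
#'   no-new-work cycles are exercised too).
#' @param closure Run referenced-object closure each cycle?
#' @return List with `reports` (all cycle reports, in order) and `state`.
#' @export
run_backup_days <- function(clinic, n_days, state_dir,
                            max_retries = 7L, cycles_per_day = 2L,
                            closure = TRUE) {
  state <- backup_state(state_dir)
  reports <- list()
  for (d in seq_len(n_days)) {
    date <- clinic$current_date + 1L
    advance_day(clinic, date)
    for (cy in seq_len(cycles_per_day)) {
      reports[[length(reports) + 1L]] <- run_cycle(
        clinic$source, clinic$archive, state, now = date,
        max_retries = max_retries, closure = closure
      )
    }
  }
  list(reports = reports, state = state)
}
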