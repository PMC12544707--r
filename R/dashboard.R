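#' Calendar-month subtraction with day clamping
#'
#' Steps a date back `n` calendar months, clamping the day-of-month to the
#' target month's length (e.g. March 31 minus two months is January 31, but
#' May 31 minus three months is February 28/29). This is the arithmetic
#' behind the dashboard's study-date lookback window.
#'
#' @param date A `Date`.
#' @param n Non-negative integer number of months.
#' @return A `Date`.
#' @examples
#' months_before(as.Date("2024-03-31"), 2)
#' months_before(as.Date("2024-05-31"), 3)
#' @export
months_before <- function(date, n) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  total <- lt$year * 12L + lt$mon - as.integer(n)
  y <- total %/% 12L
  m <- total %% 12L
  first <- as.Date(sprintf("%04d-%02d-01", y + 1900L, m + 1L))
  last_day <- as.POSIXlt(seq(first, by = "1 month", length.out = 2L)[2L] - 1L)$mday
  first + (pmin(lt$mday, last_day) - 1L)
}

#' Query the archive for candidate on-treatment records
#'
#' The roster is rebuilt from the archive alone, which supports only
#' hierarchical querying, so the descent is level by level: a study-level
#' query windowed on the study date (the simulation-CT creation date),
#' spanning the two calendar months before `reference_date` so long
#' treatment courses are not missed; then the treatment-record series of
#' each admitted study; then their record instances, whose metadata is
#' extracted. Both window endpoints are inclusive.
#'
#' @param archive Archive [dicom_store()].
#' @param reference_date Roster date (`Date`).
#' @param lookback_months Width of the study-date window in calendar months
#'   (default 2).
#' @return Tibble of [extract_record_meta()] rows (zero rows for an empty
#'   archive).
#' @export
query_candidate_records <- function(archive, reference_date,
                                    lookback_months = 2L) {
  reference_date <- as.Date(reference_date)
  window <- c(da_format(months_before(reference_date, lookback_months)),
              da_format(reference_date))
  out <- list()
  patients <- store_find(archive, "PATIENT")
  for (p in patients) {
    studies <- store_find(
      archive, "STUDY",
      parent_keys = list(PatientID = p$PatientID),
      match_keys = list(StudyDate = window)
    )
    for (st in studies) {
      series <- store_find(
        archive, "SERIES",
        parent_keys = list(PatientID = st$PatientID,
                           StudyInstanceUID = st$StudyInstanceUID),
        match_keys = list(Modality = "RTRECORD")
      )
      for (se in series) {
        inst <- store_find(
          archive, "INSTANCE",
          parent_keys = list(PatientID = se$PatientID,
                             StudyInstanceUID = se$StudyInstanceUID,
                             SeriesInstanceUID = se$SeriesInstanceUID)
        )
        for (a in inst) out[[length(out) + 1L]] <- extract_record_meta(a)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      instance_uid = character(), patient_id = character(),
      patient_name = character(), birth_date = as.Date(character()),
      physician = character(), referenced_plan_uid = character(),
      treatment_date = as.Date(character()), treatment_time = character(),
      fraction_number = integer()
    ))
  }
  dplyr::bind_rows(out)
}

#' A plan-metadata lookup backed by a store
#'
#' Returns a function mapping a plan UID to its [extract_plan_meta()] row by
#' locating the plan in `store`, or `NULL` when the plan is not archived —
#' the shape [select_current()] expects.
#'
#' @param store A [dicom_store()] holding archived plans.
#' @export
store_plan_lookup <- function(store) {
  function(uid) {
    loc <- try_locate(store, uid)
    if (is.null(loc)) return(NULL)
    extract_plan_meta(store_get_instance(store, loc))
  }
}

#' Reduce candidate records to the on-treatment roster
#'
#' A patient is currently being treated when they have not completed all
#' planned fractions and their most recent fraction was delivered within the
#' past seven days. Per (patient, plan) the most recent record — by treatment
#' date, then time — is kept, so each roster line references one plan;
#' a patient on several plans contributes one line per plan, grouped
#' together. A course whose current fraction has reached the plan's fraction
#' count is complete and dropped; a course whose last fraction is older than
#' `recency_days` is dropped (a last fraction exactly `recency_days` old is
#' kept — the boundary is inclusive). A record whose plan cannot be resolved
#' from the archive keeps its row with `fractions_planned = NA` and a
#' warning: visibility over silent omission.
#'
#' @param records Tibble from [query_candidate_records()].
#' @param reference_date Roster date (`Date`).
#' @param plan_lookup Function from plan UID to [extract_plan_meta()] row or
#'   `NULL`, e.g. [store_plan_lookup()].
#' @param recency_days Width of the recency window in days (default 7).
#' @return Tibble of roster rows: `patient_name`, `mrn`, `dob`, `physician`,
#'   `plan_label`, `fractions_planned`, `current_fraction`,
#'   `last_treatment_date`; patients ordered by name then MRN, a patient's
#'   plans by label (rows per patient contiguous).
#' @export
select_current <- function(records, reference_date, plan_lookup,
                           recency_days = 7L) {
  reference_date <- as.Date(reference_date)
  empty <- tibble::tibble(
    patient_name = character(), mrn = character(), dob = as.Date(character()),
    physician = character(), plan_label = character(),
    fractions_planned = integer(), current_fraction = integer(),
    last_treatment_date = as.Date(character())
  )
  if (nrow(records) == 0L) return(empty)

  latest <- records |>
    dplyr::group_by(.data$patient_id, .data$referenced_plan_uid) |>
    dplyr::arrange(.data$treatment_date, .data$treatment_time,
                   .by_group = TRUE) |>
    dplyr::slice_tail(n = 1L) |>
    dplyr::ungroup()

  plans <- purrr::map(latest$referenced_plan_uid, plan_lookup)
  unresolved <- purrr::map_lgl(plans, is.null)
  if (any(unresolved)) {
    rlang::warn(sprintf(
      "%d roster row(s) reference a plan missing from the archive; fractions planned unknown",
      sum(unresolved)
    ), class = "rt_dashboard_warning")
  }
  latest$fractions_planned <- purrr::map_int(
    plans, \(p) if (is.null(p)) NA_integer_ else p$fractions_planned
  )
  latest$plan_label <- purrr::map_chr(
    plans, \(p) if (is.null(p)) "" else p$plan_label
  )

  latest |>
    dplyr::filter(
      is.na(.data$fractions_planned) |
        .data$fraction_number < .data$fractions_planned,
      as.numeric(reference_date - .data$treatment_date) <= recency_days,
      .data$treatment_date <= reference_date
    ) |>
    dplyr::transmute(
      patient_name = .data$patient_name,
      mrn = .data$patient_id,
      dob = .data$birth_date,
      physician = .data$physician,
      plan_label = .data$plan_label,
      fractions_planned = .data$fractions_planned,
      current_fraction = .data$fraction_number,
      last_treatment_date = .data$treatment_date
    ) |>
    dplyr::arrange(.data$patient_name, .data$mrn, .data$plan_label)
}

#' Build the on-treatment roster directly from an archive
#'
#' Composition of [query_candidate_records()], [store_plan_lookup()] and
#' [select_current()] — the disaster-mode entry point that touches only the
#' archive.
#'
#' @inheritParams query_candidate_records
#' @inheritParams select_current
#' @export
build_dashboard <- function(archive, reference_date,
                            lookback_months = 2L, recency_days = 7L) {
  records <- query_candidate_records(archive, reference_date,
                                     lookback_months = lookback_months)
  select_current(records, reference_date, store_plan_lookup(archive),
                 recency_days = recency_days)
}

dashboard_header <- c("PatientName", "MRN", "DOB", "Physician", "PlanLabel",
                      "FractionsPlanned", "CurrentFraction",
                      "LastTreatmentDate")

#' Write the roster to the recovery dashboard CSV
#'
#' RFC-4180 CSV with the fixed header
#' `PatientName,MRN,DOB,Physician,PlanLabel,FractionsPlanned,CurrentFraction,LastTreatmentDate`,
#' ISO-8601 dates, and deterministic row order — readable in any text viewer
#' when nothing else in the clinic is running.
#'
#' @param rows Tibble from [select_current()] / [build_dashboard()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dashboard <- function(rows, path) {
  out <- tibble::tibble(
    PatientName = rows$patient_name,
    MRN = rows$mrn,
    DOB = format(rows$dob, "%Y-%m-%d"),
    Physician = rows$physician,
    PlanLabel = rows$plan_label,
    FractionsPlanned = rows$fractions_planned,
    CurrentFraction = rows$current_fraction,
    LastTreatmentDate = format(rows$last_treatment_date, "%Y-%m-%d")
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a dashboard CSV back into roster rows
#'
#' Inverse of [write_dashboard()]; `parse(write(rows))` is the identity.
#'
#' @param path Dashboard CSV path.
#' @export
read_dashboard <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      PatientName = readr::col_character(),
      MRN = readr::col_character(),
      DOB = readr::col_date(),
      Physician = readr::col_character(),
      PlanLabel = readr::col_character(),
      FractionsPlanned = readr::col_integer(),
      CurrentFraction = readr::col_integer(),
      LastTreatmentDate = readr::col_date()
    )
  )
  chr0 <- function(x) dplyr::coalesce(x, "")
  tibble::tibble(
    patient_name = chr0(out$PatientName),
    mrn = chr0(out$MRN), dob = out$DOB, physician = chr0(out$Physician),
    plan_label = chr0(out$PlanLabel),
    fractions_planned = out$FractionsPlanned,
    current_fraction = out$CurrentFraction,
    last_treatment_date = out$LastTreatmentDate
  )
}
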