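#' Open the persistent engine state for a state directory
#'
#' Bundles the daily journal and the global failure log. The journal is
#' rolled automatically by [run_cycle()] when the calendar date changes.
#'
#' @param dir State directory (created if needed).
#' @return An `rt_backup_state` environment.
#' @export
backup_state <- function(dir) {
  st <- new.env(parent = emptyenv())
  st$dir <- dir
  st$journal <- NULL
  st$failure_log <- failure_log_open(dir)
  class(st) <- "rt_backup_state"
  st
}

#' UIDs of all treatment records a source reports for one date
#'
#' Issues the day's record query against the record-and-verify source: an
#' instance-level query filtered by modality and treatment date. Records
#' cannot be queried by treatment time, so the filter is by date only; the
#' short cycle interval bounds the data at risk instead. The result carries
#' no duplicates.
#'
#' @param store Source [dicom_store()] (relaxed querying).
#' @param date Treatment date (`Date`).
#' @return Character vector of SOP instance UIDs, sorted.
#' @export
query_day_records <- function(store, date) {
  hits <- store_find(
    store, "INSTANCE",
    match_keys = list(Modality = "RTRECORD", TreatmentDate = da_format(date)),
    return_keys = "SOPInstanceUID"
  )
  sort(unique(vapply(hits, function(a) a$SOPInstanceUID, character(1))))
}

#' Transfer one record with bounded retry
#'
#' Attempts the move up to `1 + max_retries` times, stopping at the first
#' success. Transfer failure is a result value, never an exception. The
#' default of seven retries after the initial attempt (eight attempts in
#' total) is the engine's retry budget before a record is handed to the
#' failure log.
#'
#' @param uid SOP instance UID of the record at the source.
#' @param source,destination [dicom_store()] handles.
#' @param max_retries Retries after the first attempt (default 7).
#' @param path Optional known [hierarchy_path()]; located at the source when
#'   omitted.
#' @return List with `status` (final move status), `instance_uid`, and
#'   `attempts` (total attempts made).
#' @export
transfer_with_retry <- function(uid, source, destination, max_retries = 7L,
                                path = NULL) {
  if (is.null(path)) path <- locate_instance(source, uid)
  attempts <- 0L
  status <- NA_character_
  for (i in seq_len(1L + max_retries)) {
    res <- store_move(source, destination, path)
    attempts <- attempts + 1L
    status <- res$status
    if (status == "SUCCESS") break
  }
  list(status = status, instance_uid = uid, attempts = attempts)
}

#' Run one backup cycle
#'
#' One tick of the recurring backup loop: query the day's treatment records
#' from the source, drop those already journalled today, transfer each new
#' record with bounded retry, reconcile the journal and failure log, and —
#' unless disabled — close the referenced-object chain of every record
#' archived this cycle. A record absent from today's journal but already
#' present at the destination (e.g. archived in yesterday's journal around
#' midnight) is journalled without a transfer, so cross-midnight duplicates
#' are impossible. A source connection failure aborts the cycle with an
#' error-flagged report; the next tick retries. A destination that refuses
#' every transfer sends all new records to the failure log.
#'
#' @param source Source [dicom_store()].
#' @param destination Archive [dicom_store()].
#' @param state [backup_state()] (journal rolled to `now`'s date as needed).
#' @param now Timestamp of the cycle (`POSIXct` or `Date`).
#' @param max_retries Per-record retry budget (default 7).
#' @param closure Run referenced-object closure for this cycle's records?
#' @param sources Ordered source handles for closure recovery; defaults to
#'   `list(source)`.
#' @return An `rt_cycle_report`: list with `date`, `time`, `n_queried`,
#'   `n_new`, `n_succeeded`, `failed` (tibble `uid`/`attempts`/`last_status`),
#'   `closure` (tibble from [close_record_references()]), `error`.
#' @export
run_cycle <- function(source, destination, state, now = Sys.time(),
                      max_retries = 7L, closure = TRUE, sources = NULL) {
  date <- as.Date(now, tz = "")
  if (is.null(state$journal) || !identical(state$journal$date, date)) {
    state$journal <- journal_open(state$dir, date)
  }
  journal <- state$journal
  flog <- state$failure_log
  if (is.null(sources)) sources <- list(source)

  empty_failed <- tibble::tibble(uid = character(), attempts = integer(),
                                 last_status = character())
  empty_closure <- tibble::tibble(record_uid = character(), kind = character(),
                                  uid = character(), status = character(),
                                  n_instances = integer())

  # the day query returns the hierarchy identifiers alongside each UID, so
  # transfers address records directly instead of re-searching for them
  queried <- tryCatch({
    hits <- store_find(
      source, "INSTANCE",
      match_keys = list(Modality = "RTRECORD", TreatmentDate = da_format(date))
    )
    paths <- stats::setNames(
      lapply(hits, function(a) {
        hierarchy_path(a$PatientID, a$StudyInstanceUID, a$SeriesInstanceUID,
                       a$SOPInstanceUID)
      }),
      vapply(hits, function(a) a$SOPInstanceUID, character(1))
    )
    sort(unique(names(paths)))
  },
    rt_connection_error = function(e) e
  )
  if (inherits(queried, "condition")) {
    report <- new_cycle_report(date, now, n_queried = 0L, n_new = 0L,
                               n_succeeded = 0L, failed = empty_failed,
                               closure = empty_closure,
                               error = conditionMessage(queried))
    persist_cycle_report(state, report)
    return(report)
  }

  new_uids <- setdiff(queried, journal_uids(journal))
  n_succeeded <- 0L
  failed <- list()
  archived_this_cycle <- character()

  for (uid in new_uids) {
    if (store_has_instance(destination, uid)) {
      journal_append(journal, uid, now)
      failure_log_resolve(flog, uid, now)
      n_succeeded <- n_succeeded + 1L
      archived_this_cycle <- c(archived_this_cycle, uid)
      next
    }
    res <- tryCatch(
      transfer_with_retry(uid, source, destination, max_retries = max_retries,
                          path = paths[[uid]]),
      rt_connection_error = function(e) {
        list(status = "CONNECTION_FAILED", instance_uid = uid, attempts = 1L)
      }
    )
    if (res$status == "SUCCESS") {
      journal_append(journal, uid, now)
      failure_log_resolve(flog, uid, now)
      n_succeeded <- n_succeeded + 1L
      archived_this_cycle <- c(archived_this_cycle, uid)
    } else {
      failure_log_record(flog, uid, res$attempts, res$status, now)
      failed[[length(failed) + 1L]] <- tibble::tibble(
        uid = uid, attempts = res$attempts, last_status = res$status
      )
    }
  }

  closure_res <- empty_closure
  if (closure && length(archived_this_cycle)) {
    hints_by_uid <- lapply(paths[archived_this_cycle], function(p) {
      list(patient_id = p$patient_id)
    })
    closure_res <- close_record_references(archived_this_cycle, sources,
                                           destination,
                                           hints_by_uid = hints_by_uid)
  }

  report <- new_cycle_report(
    date, now,
    n_queried = length(queried),
    n_new = length(new_uids),
    n_succeeded = n_succeeded,
    failed = if (length(failed)) dplyr::bind_rows(failed) else empty_failed,
    closure = closure_res,
    error = NULL
  )
  persist_cycle_report(state, report)
  report
}

new_cycle_report <- function(date, now, n_queried, n_new, n_succeeded,
                             failed, closure, error) {
  structure(
    list(date = date, time = format(now, "%Y-%m-%dT%H:%M:%S"),
         n_queried = n_queried, n_new = n_new, n_succeeded = n_succeeded,
         failed = failed, closure = closure, error = error),
    class = "rt_cycle_report"
  )
}

#' @export
print.rt_cycle_report <- function(x, ...) {
  cat(sprintf("<backup cycle %s> queried %d, new %d, succeeded %d, failed %d%s\n",
              x$date, x$n_queried, x$n_new, x$n_succeeded, nrow(x$failed),
              if (!is.null(x$error)) paste0(" [ERROR: ", x$error, "]") else ""))
  invisible(x)
}

# Cycle summaries are persisted per day so the daily report can be rebuilt
# by a separate process (the nightly report command).
persist_cycle_report <- function(state, report) {
  path <- file.path(state$dir, sprintf("cycles-%s.jsonl", da_format(report$date)))
  line <- jsonlite::toJSON(
    list(date = as.character(report$date), time = report$time,
         n_queried = report$n_queried, n_new = report$n_new,
         n_succeeded = report$n_succeeded,
         failed = report$failed,
         n_recovered = sum(report$closure$status == "SUCCESS"),
         n_unrecoverable = sum(report$closure$status == "UNRECOVERABLE"),
         error = report$error),
    auto_unbox = TRUE, dataframe = "rows", null = "null"
  )
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

read_cycle_reports <- function(dir, date) {
  path <- file.path(dir, sprintf("cycles-%s.jsonl", da_format(date)))
  if (!file.exists(path)) return(list())
  lapply(readLines(path, warn = FALSE), jsonlite::fromJSON,
         simplifyDataFrame = FALSE)
}

#' Emit the daily backup report
#'
#' Aggregates one day's cycle reports into the operational summary the tool
#' mails out nightly in clinical deployment: total successful backups and
#' per-failure detail (the transport here is a file or standard output).
#' A day with zero executed cycles is flagged loudly — a quiet day during
#' clinical operations is the signature of a dead backup process, not of a
#' healthy one.
#'
#' @param reports List of `rt_cycle_report` objects sharing one date, or a
#'   state directory path from which the day's persisted cycle summaries are
#'   read.
#' @param date Report date; required when `reports` is a directory.
#' @param dir Output directory for `report-YYYYMMDD.txt` and `.json`;
#'   `NULL` prints the text form.
#' @return Invisibly, a list with `date`, `n_cycles`, `n_succeeded`,
#'   `failures` (tibble), `no_cycles` flag, and `text`.
#' @export
emit_daily_report <- function(reports, date = NULL, dir = NULL) {
  if (is.character(reports)) {
    stopifnot(!is.null(date))
    reports <- read_cycle_reports(reports, date)
    date <- as.Date(date)
  } else {
    dates <- unique(vapply(reports, function(r) as.character(r$date),
                           character(1)))
    if (length(dates) > 1L) {
      rt_abort("rt_report_error",
               sprintf("cycle reports span several dates: %s",
                       paste(dates, collapse = ", ")))
    }
    date <- if (length(dates)) as.Date(dates) else as.Date(date)
  }

  n_cycles <- length(reports)
  n_succeeded <- sum(vapply(reports, function(r) as.integer(r$n_succeeded),
                            integer(1)))
  fail_rows <- lapply(reports, function(r) {
    f <- r$failed
    if (is.data.frame(f)) tibble::as_tibble(f)
    else if (length(f)) dplyr::bind_rows(lapply(f, tibble::as_tibble))
    else NULL
  })
  failures <- dplyr::bind_rows(fail_rows)
  if (nrow(failures) == 0L) {
    failures <- tibble::tibble(uid = character(), attempts = integer(),
                               last_status = character())
  } else {
    # a UID may fail in several cycles; report its final state
    failures <- failures |>
      dplyr::group_by(.data$uid) |>
      dplyr::summarise(attempts = dplyr::last(.data$attempts),
                       last_status = dplyr::last(.data$last_status),
                       .groups = "drop") |>
      dplyr::arrange(.data$uid)
  }

  no_cycles <- n_cycles == 0L
  lines <- c(
    sprintf("Backup report for %s", format(date)),
    sprintf("Cycles executed: %d", n_cycles),
    sprintf("Successful backups: %d", n_succeeded),
    if (no_cycles) "WARNING: no cycles executed today - backup tool may be non-operational",
    if (nrow(failures) == 0L) "Failed backups: none" else c(
      sprintf("Failed backups: %d", nrow(failures)),
      sprintf("  %s  attempts=%d  last_status=%s",
              failures$uid, failures$attempts, failures$last_status)
    )
  )
  text <- paste(lines, collapse = "\n")

  summary <- list(date = date, n_cycles = n_cycles, n_succeeded = n_succeeded,
                  failures = failures, no_cycles = no_cycles, text = text)
  if (is.null(dir)) {
    cat(text, "\n", sep = "")
  } else {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(dir, sprintf("report-%s", da_format(date)))
    writeLines(text, paste0(stem, ".txt"))
    jsonlite::write_json(
      list(date = as.character(date), n_cycles = n_cycles,
           n_succeeded = n_succeeded, no_cycles = no_cycles,
           failures = failures),
      paste0(stem, ".json"),
      auto_unbox = TRUE, dataframe = "rows", digits = NA
    )
  }
  invisible(summary)
}
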