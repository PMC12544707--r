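#' Open (or resume) the daily backup journal
#'
#' The journal is the per-day ledger of successfully archived treatment-record
#' UIDs, used to deduplicate transfers within a day. It is persisted as
#' line-oriented JSON (`journal-YYYYMMDD.jsonl`, one `{"uid": ..., "time": ...}`
#' object per line) and appended after every successful transfer, so a crash
#' between transfers loses nothing: re-opening the same day's journal resumes
#' where the last success left off. A fresh calendar date gets a fresh, empty
#' journal file.
#'
#' @param dir State directory holding journal and failure-log files.
#' @param date Calendar date of the journal (`Date`).
#' @return A `rt_journal` environment with fields `date`, `uids`, `path`.
#' @export
journal_open <- function(dir, date) {
  date <- as.Date(date)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, sprintf("journal-%s.jsonl", da_format(date)))
  uids <- character()
  if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    uids <- vapply(lines[nzchar(lines)],
                   function(l) jsonlite::fromJSON(l)$uid, character(1),
                   USE.NAMES = FALSE)
  }
  j <- new.env(parent = emptyenv())
  j$date <- date
  j$uids <- unique(uids)
  j$path <- path
  class(j) <- "rt_journal"
  j
}

#' Record one successful backup in the journal
#'
#' Appends the UID to the journal file immediately (crash safety) and to the
#' in-memory set. Appending a UID already present is a no-op.
#'
#' @param journal An [journal_open()] object.
#' @param uid Treatment-record SOP instance UID.
#' @param time Timestamp recorded alongside the UID.
#' @export
journal_append <- function(journal, uid, time = Sys.time()) {
  if (uid %in% journal$uids) return(invisible(journal))
  line <- jsonlite::toJSON(
    list(uid = uid, time = format(time, "%Y-%m-%dT%H:%M:%S")),
    auto_unbox = TRUE
  )
  cat(line, "\n", sep = "", file = journal$path, append = TRUE)
  journal$uids <- c(journal$uids, uid)
  invisible(journal)
}

#' UIDs recorded in a journal
#' @param journal An [journal_open()] object.
#' @export
journal_uids <- function(journal) journal$uids

#' Open (or resume) the global failed-transfer log
#'
#' The failure log records every treatment record whose transfer exhausted its
#' retries, keyed by instance UID, with the first-failure timestamp, the
#' cumulative attempt count and the last transfer status. Unlike the journal
#' it is global, not per-day: a record that fails near midnight and is
#' re-queried on the next date is still reconciled. Persistence is
#' append-only event lines (`failures.jsonl`): a `failed` event upserts an
#' entry, a `resolved` event removes it; the current state is the fold of all
#' events, which keeps writes crash-safe.
#'
#' @param dir State directory.
#' @return A `rt_failure_log` environment with fields `entries`, `path`.
#' @export
failure_log_open <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "failures.jsonl")
  entries <- list()
  if (file.exists(path)) {
    for (l in readLines(path, warn = FALSE)) {
      if (!nzchar(l)) next
      ev <- jsonlite::fromJSON(l)
      if (identical(ev$event, "resolved")) {
        entries[[ev$uid]] <- NULL
      } else {
        prior <- entries[[ev$uid]]
        entries[[ev$uid]] <- list(
          first_failed_at = if (is.null(prior)) ev$time else prior$first_failed_at,
          attempts = ev$attempts,
          last_status = ev$last_status
        )
      }
    }
  }
  fl <- new.env(parent = emptyenv())
  fl$entries <- entries
  fl$path <- path
  class(fl) <- "rt_failure_log"
  fl
}

#' Record an exhausted transfer failure
#'
#' @param flog A [failure_log_open()] object.
#' @param uid Instance UID that failed.
#' @param attempts Total move attempts made in the failing sequence.
#' @param last_status Final `rt_move_result` status string.
#' @param time Timestamp of the failure.
#' @export
failure_log_record <- function(flog, uid, attempts, last_status,
                               time = Sys.time()) {
  stamp <- format(time, "%Y-%m-%dT%H:%M:%S")
  prior <- flog$entries[[uid]]
  entry <- list(
    first_failed_at = if (is.null(prior)) stamp else prior$first_failed_at,
    attempts = attempts,
    last_status = last_status
  )
  line <- jsonlite::toJSON(
    list(event = "failed", uid = uid, time = stamp,
         attempts = attempts, last_status = last_status),
    auto_unbox = TRUE
  )
  cat(line, "\n", sep = "", file = flog$path, append = TRUE)
  flog$entries[[uid]] <- entry
  invisible(flog)
}

#' Remove a UID from the failure log after a later successful backup
#'
#' No-op when the UID is not present.
#'
#' @inheritParams failure_log_record
#' @export
failure_log_resolve <- function(flog, uid, time = Sys.time()) {
  if (is.null(flog$entries[[uid]])) return(invisible(flog))
  line <- jsonlite::toJSON(
    list(event = "resolved", uid = uid,
         time = format(time, "%Y-%m-%dT%H:%M:%S")),
    auto_unbox = TRUE
  )
  cat(line, "\n", sep = "", file = flog$path, append = TRUE)
  flog$entries[[uid]] <- NULL
  invisible(flog)
}

#' Current failure-log entries as a tibble
#'
#' @param flog A [failure_log_open()] object.
#' @return Tibble with columns `uid`, `first_failed_at`, `attempts`,
#'   `last_status`, ordered by `uid`.
#' @export
failure_log_entries <- function(flog) {
  if (length(flog$entries) == 0L) {
    return(tibble::tibble(uid = character(), first_failed_at = character(),
                          attempts = integer(), last_status = character()))
  }
  uids <- sort(names(flog$entries))
  dplyr::bind_rows(lapply(uids, function(u) {
    e <- flog$entries[[u]]
    tibble::tibble(uid = u, first_failed_at = e$first_failed_at,
                   attempts = as.integer(e$attempts),
                   last_status = e$last_status)
  }))
}
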