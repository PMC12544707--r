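#' Audit the referenced-object chain of one archived treatment record
#'
#' A treatment record is only useful for resuming treatment together with the
#' plan it executed, that plan's structure set, and the planning CT series.
#' Clinical workflows push these to the archive at plan approval, but that
#' manual step is imperfect, so the chain must be verified. This walks the
#' record's reference chain and checks each link's existence at the
#' destination by hierarchical location (not a local index, so the audit
#' stays trustworthy after out-of-band archive changes). When a link is
#' absent from the destination, its onward references are resolved from the
#' configured source stores so the rest of the chain can still be audited;
#' a link absent from every store is flagged unrecoverable.
#'
#' @param record_uid SOP instance UID of a treatment record present at the
#'   destination.
#' @param destination Archive [dicom_store()].
#' @param sources Ordered list of source [dicom_store()] handles
#'   (record-and-verify first, then any separately configured planning
#'   system) used to resolve metadata of objects missing from the archive.
#' @return Tibble of missing links in chain order with columns `kind`, `uid`,
#'   `recoverable` (present in some source?). Zero rows when the chain is
#'   closed. Raises `rt_not_found_error` if the record itself is absent.
#' @param hints Optional partial-path hints for locating the record (see
#'   [locate_instance()]).
#' @export
audit_record <- function(record_uid, destination, sources = list(),
                         hints = list()) {
  rec_path <- locate_instance(destination, record_uid, hints)
  rec <- extract_record_meta(store_get_instance(destination, rec_path))
  # referenced plan, structure set and CT belong to the record's patient, so
  # every subsequent search is pruned to that subtree
  hints <- list(patient_id = rec_path$patient_id)

  resolve_meta <- function(uid, extractor) {
    for (st in c(list(destination), sources)) {
      hit <- try_locate(st, uid, hints)
      if (!is.null(hit)) return(extractor(store_get_instance(st, hit)))
    }
    NULL
  }
  plan_lookup <- function(uid) resolve_meta(uid, extract_plan_meta)
  struct_lookup <- function(uid) resolve_meta(uid, extract_struct_meta)

  chain <- reference_chain(rec, plan_lookup, struct_lookup)
  missing <- list()
  for (i in seq_len(nrow(chain))) {
    kind <- chain$kind[i]
    uid <- chain$uid[i]
    present <- if (kind == "CT_SERIES") {
      !is.null(try_locate_series(destination, uid, hints))
    } else {
      !is.null(try_locate(destination, uid, hints))
    }
    if (!present) {
      recoverable <- any(vapply(sources, function(st) {
        if (kind == "CT_SERIES") !is.null(try_locate_series(st, uid, hints))
        else !is.null(try_locate(st, uid, hints))
      }, logical(1)))
      missing[[length(missing) + 1L]] <- tibble::tibble(
        kind = kind, uid = uid, recoverable = recoverable,
        patient_id = rec_path$patient_id
      )
    }
  }
  if (length(missing) == 0L) {
    return(tibble::tibble(kind = character(), uid = character(),
                          recoverable = logical(),
                          patient_id = character()))
  }
  dplyr::bind_rows(missing)
}

try_locate <- function(store, uid, hints = list()) {
  tryCatch(locate_instance(store, uid, hints),
           rt_not_found_error = function(e) NULL)
}

try_locate_series <- function(store, uid, hints = list()) {
  tryCatch(locate_series(store, uid, hints),
           rt_not_found_error = function(e) NULL)
}

#' Recover missing referenced objects from the source stores
#'
#' For each missing link, in chain order (a structure set is never attempted
#' before its referencing plan, preserving the navigability of a partially
#' recovered archive): locate the object at the first source that holds it
#' and transfer it to the destination. CT recovery moves every instance of
#' the referenced series. Objects absent from every source are reported
#' unrecoverable; the remaining links are still attempted. Existing
#' destination objects are never modified or removed.
#'
#' @param missing Tibble from [audit_record()].
#' @param sources Ordered list of source [dicom_store()] handles.
#' @param destination Archive [dicom_store()].
#' @return Tibble with columns `kind`, `uid`, `status`
#'   (`"SUCCESS"`, `"TRANSFER_FAILED"`, `"CONNECTION_FAILED"` or
#'   `"UNRECOVERABLE"`) and `n_instances` moved.
#' @export
recover_missing <- function(missing, sources, destination) {
  if (nrow(missing) == 0L) {
    return(tibble::tibble(kind = character(), uid = character(),
                          status = character(), n_instances = integer()))
  }
  ord <- order(match(missing$kind, rt_chain_kinds))
  missing <- missing[ord, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(missing))) {
    kind <- missing$kind[i]
    uid <- missing$uid[i]
    hints <- if ("patient_id" %in% names(missing)) {
      list(patient_id = missing$patient_id[i])
    } else {
      list()
    }
    res <- recover_one(kind, uid, sources, destination, hints)
    out[[i]] <- tibble::tibble(kind = kind, uid = uid,
                               status = res$status,
                               n_instances = res$n_instances)
  }
  dplyr::bind_rows(out)
}

recover_one <- function(kind, uid, sources, destination, hints = list()) {
  for (src in sources) {
    if (kind == "CT_SERIES") {
      sloc <- try_locate_series(src, uid, hints)
      if (is.null(sloc)) next
      inst <- store_find(
        src, "INSTANCE",
        parent_keys = list(PatientID = sloc$patient_id,
                           StudyInstanceUID = sloc$study_uid,
                           SeriesInstanceUID = sloc$series_uid)
      )
      statuses <- character()
      for (a in inst) {
        path <- hierarchy_path(sloc$patient_id, sloc$study_uid,
                               sloc$series_uid, a$SOPInstanceUID)
        statuses <- c(statuses, store_move(src, destination, path)$status)
      }
      final <- if (all(statuses == "SUCCESS")) "SUCCESS" else
        statuses[statuses != "SUCCESS"][1L]
      return(list(status = final, n_instances = sum(statuses == "SUCCESS")))
    } else {
      loc <- try_locate(src, uid, hints)
      if (is.null(loc)) next
      res <- store_move(src, destination, loc)
      return(list(status = res$status,
                  n_instances = as.integer(res$status == "SUCCESS")))
    }
  }
  list(status = "UNRECOVERABLE", n_instances = 0L)
}

#' Audit and recover the chains of a set of archived records
#'
#' Convenience composition of [audit_record()] and [recover_missing()] used
#' by every backup cycle: after the day's records are archived, each record's
#' chain is audited and recoverable gaps are filled, so the archive converges
#' to referential closure (audit -> recover -> audit reaches an empty
#' recoverable-missing set whenever the sources hold the objects).
#'
#' @param record_uids Character vector of archived treatment-record UIDs.
#' @param sources Ordered list of source [dicom_store()] handles.
#' @param destination Archive [dicom_store()].
#' @param hints_by_uid Optional named list of per-record locate hints, e.g.
#'   the hierarchy paths the backup cycle just transferred.
#' @return Tibble with one row per missing link found, columns `record_uid`,
#'   `kind`, `uid`, `status`, `n_instances`.
#' @export
close_record_references <- function(record_uids, sources, destination,
                                    hints_by_uid = list()) {
  out <- list()
  for (ruid in record_uids) {
    missing <- audit_record(ruid, destination, sources,
                            hints = hints_by_uid[[ruid]] %||% list())
    if (nrow(missing) == 0L) next
    res <- recover_missing(missing, sources, destination)
    res$record_uid <- ruid
    out[[length(out) + 1L]] <- res
  }
  if (length(out) == 0L) {
    return(tibble::tibble(record_uid = character(), kind = character(),
                          uid = character(), status = character(),
                          n_instances = integer()))
  }
  dplyr::relocate(dplyr::bind_rows(out), "record_uid")
}
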