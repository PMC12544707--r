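#' In-memory hierarchical DICOM store
#'
#' Creates a mutable store implementing the query/retrieve contract used by
#' every other component: level-scoped `FIND` ([store_find()]) and per-instance
#' `MOVE` ([store_move()]) with scripted transfer faults. The store models the
#' Patient / Study / Series / Instance information hierarchy of a DICOM
#' archive. A store created with `hierarchical_only = TRUE` behaves like an
#' RT-PACS that supports only hierarchical querying: a query at one level must
#' supply the identifiers of every level above it, which is what forces the
#' breadth-first locator into existence. With `hierarchical_only = FALSE` the
#' store additionally answers unscoped instance-level queries, like a
#' record-and-verify system that can be asked directly for a day's treatment
#' records.
#'
#' @param label Human-readable store name used in error messages and logs.
#' @param hierarchical_only Enforce hierarchical query discipline in
#'   [store_find()]?
#' @return A `dicom_store` object (environment-backed; modified in place).
#' @examples
#' s <- dicom_store("rv", hierarchical_only = FALSE)
#' store_instance_count(s)
#' @export
dicom_store <- function(label = "store", hierarchical_only = TRUE) {
  store <- new.env(parent = emptyenv())
  store$label <- label
  store$hierarchical_only <- isTRUE(hierarchical_only)
  store$patients <- list()
  store$down <- FALSE
  store$fault <- list(mode = "NONE", k = 0L)
  store$fault_counts <- integer()
  store$n_find <- 0L
  store$n_move_out <- 0L
  store$success_moves <- integer() # per-UID count of successful inbound moves
  class(store) <- "dicom_store"
  store
}

#' @export
print.dicom_store <- function(x, ...) {
  cat(sprintf(
    "<dicom_store '%s'> %d patients, %d instances, %s querying\n",
    x$label, length(x$patients), store_instance_count(x),
    if (x$hierarchical_only) "hierarchical-only" else "relaxed"
  ))
  invisible(x)
}

#' Scripted fault policy for transfer testing
#'
#' Describes how a store misbehaves during [store_move()]: never
#' (`"NONE"`), for the first `k` attempts on each instance
#' (`"FAIL_FIRST_K"`), always (`"FAIL_ALWAYS"`), or by refusing the
#' association entirely (`"CONNECTION_DOWN"`). Faults are counted per
#' instance UID so interleaved transfers of several records play back
#' deterministically. `FAIL_FIRST_K` with `k = 0` is equivalent to `NONE`.
#'
#' @param mode One of `"NONE"`, `"FAIL_FIRST_K"`, `"FAIL_ALWAYS"`,
#'   `"CONNECTION_DOWN"`.
#' @param k Number of initial failing attempts per instance (only used by
#'   `FAIL_FIRST_K`).
#' @export
fault_policy <- function(mode = c("NONE", "FAIL_FIRST_K", "FAIL_ALWAYS",
                                  "CONNECTION_DOWN"),
                         k = 0L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (is.na(k) || k < 0L) {
    rt_abort("rt_config_error", "fault_policy k must be a non-negative integer")
  }
  list(mode = mode, k = k)
}

#' Attach a fault policy to a store
#'
#' The policy governs subsequent inbound transfers to `store`. Attempt
#' counters are reset.
#'
#' @param store A [dicom_store()].
#' @param policy A [fault_policy()].
#' @export
store_set_fault_policy <- function(store, policy) {
  store$fault <- policy
  store$fault_counts <- integer()
  invisible(store)
}

#' Mark a store's network connection up or down
#'
#' While down, both [store_find()] and [store_move()] raise a structured
#' `rt_connection_error`, modelling an unreachable DICOM peer.
#'
#' @param store A [dicom_store()].
#' @param down Logical.
#' @export
store_set_connection <- function(store, down = TRUE) {
  store$down <- isTRUE(down)
  invisible(store)
}

check_connection <- function(store) {
  if (isTRUE(store$down)) {
    rt_abort("rt_connection_error",
             sprintf("connection to store '%s' refused", store$label))
  }
}

#' Insert one instance into a store
#'
#' The attribute set must carry the full four-level address
#' (`PatientID`, `StudyInstanceUID`, `SeriesInstanceUID`, `SOPInstanceUID`)
#' plus `StudyDate` and `Modality`, from which the patient, study and series
#' nodes are created on demand. Re-inserting an existing SOP instance UID
#' silently overwrites (duplicate-safe storage).
#'
#' @param store A [dicom_store()].
#' @param attrs Named list of DICOM attributes for one instance.
#' @export
store_put <- function(store, attrs) {
  pid  <- require_attr(attrs, "PatientID")
  suid <- require_attr(attrs, "StudyInstanceUID")
  seid <- require_attr(attrs, "SeriesInstanceUID")
  iuid <- require_attr(attrs, "SOPInstanceUID")
  if (is.null(store$patients[[pid]])) {
    store$patients[[pid]] <- list(
      attrs = list(PatientID = pid,
                   PatientName = attr_or(attrs, "PatientName", "")),
      studies = list()
    )
  }
  if (is.null(store$patients[[pid]]$studies[[suid]])) {
    store$patients[[pid]]$studies[[suid]] <- list(
      attrs = list(PatientID = pid, StudyInstanceUID = suid,
                   StudyDate = attr_or(attrs, "StudyDate", "")),
      series = list()
    )
  }
  if (is.null(store$patients[[pid]]$studies[[suid]]$series[[seid]])) {
    store$patients[[pid]]$studies[[suid]]$series[[seid]] <- list(
      attrs = list(PatientID = pid, StudyInstanceUID = suid,
                   SeriesInstanceUID = seid,
                   Modality = attr_or(attrs, "Modality", "")),
      instances = list()
    )
  }
  store$patients[[pid]]$studies[[suid]]$series[[seid]]$instances[[iuid]] <- attrs
  invisible(store)
}

#' Does an instance exist in a store?
#'
#' Direct index lookup by SOP instance UID, bypassing the query contract.
#' Intended for engine-internal existence checks and test oracles.
#'
#' @param store A [dicom_store()].
#' @param instance_uid SOP instance UID.
#' @export
store_has_instance <- function(store, instance_uid) {
  for (p in store$patients)
    for (st in p$studies)
      for (se in st$series)
        if (!is.null(se$instances[[instance_uid]])) return(TRUE)
  FALSE
}

#' Enumerate every instance in a store
#'
#' Returns the exhaustive flat view of the hierarchy — one row per instance
#' with its four-level address and attribute set. This deliberately bypasses
#' the query contract; it is the brute-force oracle that the breadth-first
#' locator and the dashboard pipeline are tested against, and the basis of
#' store serialization.
#'
#' @param store A [dicom_store()].
#' @return A tibble with columns `patient_id`, `study_uid`, `series_uid`,
#'   `instance_uid`, `study_date`, `modality`, `sop_class` and a list-column
#'   `attrs`.
#' @export
store_instances <- function(store) {
  rows <- list()
  for (pid in sort(names(store$patients))) {
    p <- store$patients[[pid]]
    for (suid in sort(names(p$studies))) {
      st <- p$studies[[suid]]
      for (seid in sort(names(st$series))) {
        se <- st$series[[seid]]
        for (iuid in sort(names(se$instances))) {
          a <- se$instances[[iuid]]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            patient_id = pid, study_uid = suid, series_uid = seid,
            instance_uid = iuid,
            study_date = attr_or(st$attrs, "StudyDate", ""),
            modality = attr_or(se$attrs, "Modality", ""),
            sop_class = attr_or(a, "SOPClassUID", ""),
            attrs = list(a)
          )
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      patient_id = character(), study_uid = character(),
      series_uid = character(), instance_uid = character(),
      study_date = character(), modality = character(),
      sop_class = character(), attrs = list()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Number of instances held by a store
#' @param store A [dicom_store()].
#' @export
store_instance_count <- function(store) {
  n <- 0L
  for (p in store$patients)
    for (st in p$studies)
      for (se in st$series) n <- n + length(se$instances)
  n
}

#' Fetch the attribute set of one instance by its hierarchy path
#'
#' @param store A [dicom_store()].
#' @param path A one-row [hierarchy_path()] tibble.
#' @export
store_get_instance <- function(store, path) {
  se <- store$patients[[path$patient_id]]$studies[[path$study_uid]]$series[[path$series_uid]]
  a <- se$instances[[path$instance_uid]]
  if (is.null(a)) {
    rt_abort("rt_not_found_error",
             sprintf("instance %s not found at path in store '%s'",
                     path$instance_uid, store$label))
  }
  a
}

# query ------------------------------------------------------------------

level_rank <- function(level) match(level, rt_query_levels)

required_parents <- list(
  PATIENT  = character(),
  STUDY    = "PatientID",
  SERIES   = c("PatientID", "StudyInstanceUID"),
  INSTANCE = c("PatientID", "StudyInstanceUID", "SeriesInstanceUID")
)

match_one <- function(attrs, key, want) {
  have <- attrs[[key]]
  if (is.null(have)) return(FALSE)
  # length-2 value on a DA attribute means an inclusive date range
  if (length(want) == 2L && grepl("Date$", key)) {
    d <- da_parse(have, key)
    return(!is.na(d) && d >= da_parse(want[[1L]], key) &&
             d <= da_parse(want[[2L]], key))
  }
  identical(as.character(have), as.character(want))
}

matches_all <- function(attrs, match_keys) {
  for (key in names(match_keys)) {
    if (!match_one(attrs, key, match_keys[[key]])) return(FALSE)
  }
  TRUE
}

#' Level-scoped query against a store (C-FIND analogue)
#'
#' Returns one attribute set per entity matching `match_keys` at `level`.
#' Hierarchical-only stores require `parent_keys` to identify every level
#' above `level` (`PatientID` for a study query, plus `StudyInstanceUID` for
#' series, plus `SeriesInstanceUID` for instances); violating that discipline
#' raises a structured `rt_contract_error`. Attributes ending in `Date` accept
#' a length-2 value as an inclusive range. Results are ordered
#' lexicographically by their identifiers, and repeated identical queries
#' return identical results while the store is unchanged.
#'
#' @param store A [dicom_store()].
#' @param level One of `"PATIENT"`, `"STUDY"`, `"SERIES"`, `"INSTANCE"`.
#' @param parent_keys Named list of identifiers of the levels above `level`.
#' @param match_keys Named list of attribute filters applied at `level`.
#' @param return_keys Optional character vector restricting returned
#'   attributes (identifiers are always included); `NULL` returns the full
#'   attribute set.
#' @return List of named attribute lists (possibly empty).
#' @export
store_find <- function(store, level, parent_keys = list(),
                       match_keys = list(), return_keys = NULL) {
  check_connection(store)
  level <- match.arg(level, rt_query_levels)
  if (store$hierarchical_only) {
    need <- required_parents[[level]]
    missing <- need[!vapply(need, function(k) {
      !is.null(parent_keys[[k]]) && nzchar(as.character(parent_keys[[k]]))
    }, logical(1))]
    if (length(missing)) {
      rt_abort("rt_contract_error",
               sprintf("hierarchical query at %s level requires %s",
                       level, paste(missing, collapse = ", ")))
    }
  }
  store$n_find <- store$n_find + 1L

  pids <- sort(names(store$patients))
  if (!is.null(parent_keys$PatientID)) {
    pids <- intersect(pids, as.character(parent_keys$PatientID))
  }

  out <- list()
  for (pid in pids) {
    p <- store$patients[[pid]]
    if (level == "PATIENT") {
      if (matches_all(p$attrs, match_keys)) out[[length(out) + 1L]] <- p$attrs
      next
    }
    suids <- sort(names(p$studies))
    if (!is.null(parent_keys$StudyInstanceUID)) {
      suids <- intersect(suids, as.character(parent_keys$StudyInstanceUID))
    }
    for (suid in suids) {
      st <- p$studies[[suid]]
      if (level == "STUDY") {
        if (matches_all(st$attrs, match_keys)) {
          out[[length(out) + 1L]] <- st$attrs
        }
        next
      }
      seids <- sort(names(st$series))
      if (!is.null(parent_keys$SeriesInstanceUID)) {
        seids <- intersect(seids, as.character(parent_keys$SeriesInstanceUID))
      }
      for (seid in seids) {
        se <- st$series[[seid]]
        if (level == "SERIES") {
          if (matches_all(se$attrs, match_keys)) {
            out[[length(out) + 1L]] <- se$attrs
          }
          next
        }
        for (iuid in sort(names(se$instances))) {
          a <- se$instances[[iuid]]
          if (matches_all(a, match_keys)) out[[length(out) + 1L]] <- a
        }
      }
    }
  }

  if (!is.null(return_keys)) {
    id_keys <- c("PatientID", "StudyInstanceUID", "SeriesInstanceUID",
                 "SOPInstanceUID")
    keep <- union(id_keys, return_keys)
    out <- lapply(out, function(a) a[intersect(keep, names(a))])
  }
  out
}

# transfer ---------------------------------------------------------------

#' Transfer one instance between stores (C-MOVE analogue)
#'
#' Attempts to copy the instance addressed by `path` from `source` into
#' `destination`. The destination's [fault_policy()] is consulted with a
#' per-instance attempt counter, so a `FAIL_FIRST_K` policy fails the first
#' `k` attempts for each instance and then succeeds. On success the full
#' attribute set exists at the destination under the same hierarchy; on
#' failure the destination is unchanged (transfers are atomic). Re-moving an
#' instance already present succeeds and silently overwrites.
#'
#' @param source,destination [dicom_store()] handles.
#' @param path One-row [hierarchy_path()] tibble addressing the instance at
#'   the source.
#' @return An `rt_move_result`: list with `status` (`"SUCCESS"`,
#'   `"TRANSFER_FAILED"` or `"CONNECTION_FAILED"`), `instance_uid`, and
#'   `attempt_index` (1-based per-instance attempt count).
#' @export
store_move <- function(source, destination, path) {
  check_connection(source)
  check_connection(destination)
  uid <- path$instance_uid
  attrs <- tryCatch(
    store_get_instance(source, path),
    error = function(e) {
      rt_abort("rt_not_found_error",
               sprintf("instance %s not present at source '%s'",
                       uid, source$label))
    }
  )
  source$n_move_out <- source$n_move_out + 1L

  n_prev <- attr_or(as.list(destination$fault_counts), uid, 0L)
  attempt <- n_prev + 1L
  destination$fault_counts[[uid]] <- attempt

  pol <- destination$fault
  status <- switch(
    pol$mode,
    NONE = "SUCCESS",
    FAIL_FIRST_K = if (attempt <= pol$k) "TRANSFER_FAILED" else "SUCCESS",
    FAIL_ALWAYS = "TRANSFER_FAILED",
    CONNECTION_DOWN = "CONNECTION_FAILED"
  )
  if (status == "SUCCESS") {
    store_put(destination, attrs)
    destination$success_moves[[uid]] <-
      attr_or(as.list(destination$success_moves), uid, 0L) + 1L
  }
  structure(
    list(status = status, instance_uid = uid, attempt_index = attempt),
    class = "rt_move_result"
  )
}

#' Construct a four-level hierarchy address
#'
#' @param patient_id,study_uid,series_uid,instance_uid Identifiers; the
#'   instance UID may be `NA` for a series-level address.
#' @param study_date Study date (`Date` or `YYYYMMDD` string), if known.
#' @return One-row tibble with those five columns (dates as `Date`).
#' @export
hierarchy_path <- function(patient_id, study_uid, series_uid,
                           instance_uid = NA_character_,
                           study_date = NA) {
  tibble::tibble(
    patient_id = as.character(patient_id),
    study_uid = as.character(study_uid),
    series_uid = as.character(series_uid),
    instance_uid = as.character(instance_uid),
    study_date = if (all(is.na(study_date))) as.Date(NA) else da_parse(study_date)
  )
}

# serialization ----------------------------------------------------------

#' Serialize a store to a JSON file
#'
#' Writes the flat instance view as JSON so a clinic snapshot survives as a
#' plain-text artifact that [store_read()] reconstructs exactly. Used by the
#' command-line workflow to pass stores between `simulate`, `backup` and
#' `dashboard` invocations.
#'
#' @param store A [dicom_store()].
#' @param path Output file path.
#' @export
store_write <- function(store, path) {
  inst <- store_instances(store)
  payload <- list(
    label = store$label,
    hierarchical_only = store$hierarchical_only,
    instances = inst$attrs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Read a store serialized by [store_write()]
#'
#' @param path JSON file produced by [store_write()].
#' @return A [dicom_store()] with identical contents.
#' @export
store_read <- function(path) {
  payload <- jsonlite::read_json(path)
  store <- dicom_store(label = payload$label %||% "store",
                       hierarchical_only = isTRUE(payload$hierarchical_only))
  for (attrs in payload$instances) store_put(store, attrs)
  store
}
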