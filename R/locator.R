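#' Breadth-first location of an instance in a hierarchical store
#'
#' Hierarchical archives require the identifiers of every level above an
#' object before the object itself can be queried, but the backup chain knows
#' most objects only by their SOP instance UID. This recovers the full
#' four-level address by breadth-first search over the Patient -> Study ->
#' Series -> Instance tree: it enumerates all candidate patients, then all
#' studies of those patients, then all series, and finally probes each series
#' with a UID-matched instance-level query (rather than listing every
#' instance, which halves the query volume). The frontier is expanded in
#' lexicographic identifier order, so the search is deterministic, and no
#' node is queried twice.
#'
#' Hints prune the frontier: a known `patient_id` restricts the search to one
#' patient subtree, and `study_uid` / `series_uid` cut deeper. The search
#' always completes the final level before answering so that a UID planted in
#' two subtrees — standard-violating, but seen in practice — is reported as a
#' structured ambiguity error instead of silently returning the first path,
#' which would be a patient-safety hazard.
#'
#' @param store A [dicom_store()].
#' @param uid SOP instance UID to locate.
#' @param hints Optional named list with any of `patient_id`, `study_uid`,
#'   `series_uid` to prune the search.
#' @return A one-row [hierarchy_path()] tibble with an attribute
#'   `search_stats` (list with `find_calls` and `nodes_visited`). If the UID
#'   is absent an `rt_not_found_error` is raised carrying `nodes_visited`;
#'   a duplicated UID raises an `rt_ambiguity_error` carrying all paths.
#' @export
locate_instance <- function(store, uid, hints = list()) {
  assert_uid(uid, "SOP instance UID")
  res <- bfs_search(store, hints, probe = function(parents) {
    hits <- store_find(store, "INSTANCE", parent_keys = parents,
                       match_keys = list(SOPInstanceUID = uid))
    lapply(hits, function(a) {
      hierarchy_path(parents$PatientID, parents$StudyInstanceUID,
                     parents$SeriesInstanceUID, uid,
                     study_date = parents$.study_date)
    })
  })
  finish_search(res, uid, "instance")
}

#' Breadth-first location of a series in a hierarchical store
#'
#' As [locate_instance()], but the search terminates at the series level; the
#' returned path has `instance_uid = NA`. Used to check and recover planning
#' CT series, which are handled at series granularity.
#'
#' @inheritParams locate_instance
#' @param series_uid Series instance UID to locate.
#' @export
locate_series <- function(store, series_uid, hints = list()) {
  assert_uid(series_uid, "series instance UID")
  res <- bfs_search(store, hints, series_probe = function(parents, series_attrs) {
    if (identical(series_attrs$SeriesInstanceUID, series_uid)) {
      list(hierarchy_path(parents$PatientID, parents$StudyInstanceUID,
                          series_uid, NA_character_,
                          study_date = parents$.study_date))
    } else {
      list()
    }
  })
  finish_search(res, series_uid, "series")
}

# Shared level-by-level BFS. Exactly one of `probe` (instance-level UID probe
# per candidate series) or `series_probe` (match applied to each enumerated
# series) is supplied.
bfs_search <- function(store, hints, probe = NULL, series_probe = NULL) {
  find0 <- store$n_find
  visited <- 0L
  matches <- list()

  patients <- store_find(store, "PATIENT",
                         match_keys = drop_null(list(
                           PatientID = hints$patient_id)))
  visited <- visited + length(patients)

  study_frontier <- list()
  for (p in patients) {
    studies <- store_find(
      store, "STUDY",
      parent_keys = list(PatientID = p$PatientID),
      match_keys = drop_null(list(StudyInstanceUID = hints$study_uid))
    )
    study_frontier <- c(study_frontier, studies)
  }
  visited <- visited + length(study_frontier)

  series_frontier <- list()
  for (st in study_frontier) {
    series <- store_find(
      store, "SERIES",
      parent_keys = list(PatientID = st$PatientID,
                         StudyInstanceUID = st$StudyInstanceUID),
      match_keys = drop_null(list(SeriesInstanceUID = hints$series_uid))
    )
    for (se in series) {
      se$.study_date <- attr_or(st, "StudyDate", NA)
      series_frontier[[length(series_frontier) + 1L]] <- se
    }
  }
  visited <- visited + length(series_frontier)

  for (se in series_frontier) {
    parents <- list(PatientID = se$PatientID,
                    StudyInstanceUID = se$StudyInstanceUID,
                    SeriesInstanceUID = se$SeriesInstanceUID,
                    .study_date = se$.study_date)
    hits <- if (!is.null(series_probe)) {
      series_probe(parents, se)
    } else {
      visited <- visited + 1L # one probe per candidate series
      probe(parents)
    }
    matches <- c(matches, hits)
  }

  list(matches = matches, visited = visited,
       find_calls = store$n_find - find0)
}

finish_search <- function(res, uid, what) {
  if (length(res$matches) == 0L) {
    rlang::abort(
      sprintf("%s %s not found (%d nodes visited)", what, uid, res$visited),
      class = "rt_not_found_error",
      nodes_visited = res$visited
    )
  }
  if (length(res$matches) > 1L) {
    paths <- dplyr::bind_rows(res$matches)
    rlang::abort(
      sprintf("%s UID %s is ambiguous: found at %d distinct paths",
              what, uid, nrow(paths)),
      class = "rt_ambiguity_error",
      paths = paths
    )
  }
  out <- res$matches[[1L]]
  attr(out, "search_stats") <- list(find_calls = res$find_calls,
                                    nodes_visited = res$visited)
  out
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
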