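#' SOP class UIDs for the four linked DICOM-RT object kinds
#'
#' Named list mapping the object kinds handled by the backup chain to the
#' standard SOP class UIDs used in instance attribute sets: external-beam
#' treatment record, RT plan, RT structure set, and CT image.
#'
#' @format A named list of four UID strings.
#' @export
rt_sop_classes <- list(
  TREATMENT_RECORD = "1.2.840.10008.5.1.4.1.1.481.4",
  PLAN             = "1.2.840.10008.5.1.4.1.1.481.5",
  STRUCTURE_SET    = "1.2.840.10008.5.1.4.1.1.481.3",
  CT_IMAGE         = "1.2.840.10008.5.1.4.1.1.2"
)

#' The ordered object kinds of the reference chain
#'
#' A delivered-fraction treatment record references exactly one plan, the plan
#' at most one structure set, and the structure set at most one planning CT
#' series. Chain walks always produce a prefix of this vector.
#'
#' @export
rt_chain_kinds <- c("PLAN", "STRUCTURE_SET", "CT_SERIES")

#' Query levels of the DICOM information model
#'
#' Strictly ordered PATIENT < STUDY < SERIES < INSTANCE; hierarchical servers
#' require the identifiers of every level above the one being queried.
#'
#' @export
rt_query_levels <- c("PATIENT", "STUDY", "SERIES", "INSTANCE")

#' Validate a DICOM unique identifier
#'
#' A valid UID is a non-empty dot-separated sequence of numeric components of
#' at most 64 characters.
#'
#' @param x Character vector of candidate UIDs.
#' @return Logical vector, `TRUE` where the UID is syntactically valid.
#' @examples
#' uid_valid(c("1.2.840.10008.1.1", "", "abc.1", strrep("1", 65)))
#' @export
uid_valid <- function(x) {
  ok <- !is.na(x) & nzchar(x) & nchar(x) <= 64L
  ok & grepl("^[0-9]+(\\.[0-9]+)*$", x)
}

assert_uid <- function(x, what = "UID") {
  if (length(x) != 1L || !isTRUE(uid_valid(x))) {
    rlang::abort(
      sprintf("invalid %s: %s", what, deparse1(x)),
      class = "rt_uid_error"
    )
  }
  invisible(x)
}

# DICOM DA (YYYYMMDD) <-> Date -------------------------------------------

da_parse <- function(x, attribute = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y%m%d")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    rlang::abort(
      sprintf("unparseable DICOM DA value %s in attribute %s",
              deparse1(as.character(x)[bad][1L]), attribute),
      class = "rt_extract_error", attribute = attribute
    )
  }
  out
}

da_format <- function(d) format(as.Date(d), "%Y%m%d")

# DICOM TM values are kept as zero-padded HHMMSS strings; fixed width makes
# lexicographic comparison equal to chronological comparison.
tm_validate <- function(x, attribute = "time") {
  x <- as.character(x)
  if (any(!grepl("^[0-9]{6}$", x))) {
    rlang::abort(
      sprintf("unparseable DICOM TM value %s in attribute %s",
              deparse1(x[!grepl("^[0-9]{6}$", x)][1L]), attribute),
      class = "rt_extract_error", attribute = attribute
    )
  }
  x
}

# condition helpers -------------------------------------------------------

rt_abort <- function(class, msg, ...) {
  rlang::abort(msg, class = class, ...)
}

attr_or <- function(attrs, name, default = NULL) {
  v <- attrs[[name]]
  if (is.null(v)) default else v
}

require_attr <- function(attrs, name) {
  v <- attrs[[name]]
  if (is.null(v) || (is.character(v) && !nzchar(v[1L]))) {
    rlang::abort(
      sprintf("required attribute %s is missing", name),
      class = "rt_extract_error", attribute = name
    )
  }
  v
}
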