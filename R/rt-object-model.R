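#' Extract treatment-record metadata from an instance attribute set
#'
#' Pulls the identity, course and cross-reference fields the backup and
#' dashboard pipelines need from one RT treatment record: patient identity,
#' the referenced plan UID, the treatment date/time, and the delivered
#' fraction number. The plan reference is read from the record's
#' referenced-plan sequence; the delivered fraction is the maximum
#' current-fraction number across the treated-beam session items (all beams of
#' one session share the session's fraction index, so the maximum is robust to
#' partial sessions). Physician of record falls back to the referring
#' physician, else the empty string.
#'
#' @param attrs Named list of DICOM attributes declaring the treatment-record
#'   SOP class.
#' @return One-row tibble with columns `instance_uid`, `patient_id`,
#'   `patient_name`, `birth_date` (`Date`), `physician`,
#'   `referenced_plan_uid`, `treatment_date` (`Date`), `treatment_time`
#'   (`HHMMSS` string) and `fraction_number` (integer >= 1).
#' @examples
#' rec <- list(
#'   SOPClassUID = rt_sop_classes$TREATMENT_RECORD,
#'   SOPInstanceUID = "1.2.3.1", PatientID = "ZZ000001",
#'   PatientName = "ZZTEST^P001", PatientBirthDate = "19500101",
#'   TreatmentDate = "20240502", TreatmentTime = "081500",
#'   ReferencedRTPlanSequence = list(list(ReferencedSOPInstanceUID = "1.2.3.9")),
#'   TreatmentSessionBeamSequence = list(list(CurrentFractionNumber = 3))
#' )
#' extract_record_meta(rec)
#' @export
extract_record_meta <- function(attrs) {
  if (!identical(attrs$SOPClassUID, rt_sop_classes$TREATMENT_RECORD)) {
    rlang::abort("attribute set does not declare the treatment-record SOP class",
                 class = "rt_extract_error", attribute = "SOPClassUID")
  }
  uid <- require_attr(attrs, "SOPInstanceUID")
  plan_seq <- attrs$ReferencedRTPlanSequence
  if (is.null(plan_seq) || length(plan_seq) == 0L ||
      is.null(plan_seq[[1L]]$ReferencedSOPInstanceUID)) {
    rlang::abort("treatment record lacks a referenced-plan sequence",
                 class = "rt_extract_error",
                 attribute = "ReferencedRTPlanSequence")
  }
  beams <- attrs$TreatmentSessionBeamSequence
  fracs <- vapply(beams, function(b) {
    v <- b$CurrentFractionNumber
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, integer(1))
  fracs <- fracs[!is.na(fracs)]
  if (length(fracs) == 0L) {
    rlang::abort("treatment record carries no current-fraction number",
                 class = "rt_extract_error",
                 attribute = "TreatmentSessionBeamSequence")
  }
  tibble::tibble(
    instance_uid = uid,
    patient_id = as.character(require_attr(attrs, "PatientID")),
    patient_name = as.character(attr_or(attrs, "PatientName", "")),
    birth_date = da_parse(require_attr(attrs, "PatientBirthDate"),
                          "PatientBirthDate"),
    physician = as.character(
      attr_or(attrs, "PhysiciansOfRecord",
              attr_or(attrs, "ReferringPhysicianName", ""))
    ),
    referenced_plan_uid = as.character(plan_seq[[1L]]$ReferencedSOPInstanceUID),
    treatment_date = da_parse(require_attr(attrs, "TreatmentDate"),
                              "TreatmentDate"),
    treatment_time = tm_validate(attr_or(attrs, "TreatmentTime", "000000"),
                                 "TreatmentTime"),
    fraction_number = max(fracs)
  )
}

#' Extract plan metadata from an instance attribute set
#'
#' Reads the plan label, the number of fractions planned (from the
#' fraction-group item), and the optional structure-set reference.
#'
#' @param attrs Named list of DICOM attributes declaring the RT plan SOP
#'   class.
#' @return One-row tibble with columns `instance_uid`, `plan_label`,
#'   `fractions_planned` (integer >= 1) and `referenced_struct_uid`
#'   (`NA` when the plan references no structure set).
#' @export
extract_plan_meta <- function(attrs) {
  if (!identical(attrs$SOPClassUID, rt_sop_classes$PLAN)) {
    rlang::abort("attribute set does not declare the RT plan SOP class",
                 class = "rt_extract_error", attribute = "SOPClassUID")
  }
  uid <- require_attr(attrs, "SOPInstanceUID")
  fg <- attrs$FractionGroupSequence
  nf <- if (!is.null(fg) && length(fg) > 0L) fg[[1L]]$NumberOfFractionsPlanned
  if (is.null(nf) || is.na(as.integer(nf)) || as.integer(nf) < 1L) {
    rlang::abort("plan lacks a usable number of fractions planned",
                 class = "rt_extract_error",
                 attribute = "FractionGroupSequence")
  }
  ss <- attrs$ReferencedStructureSetSequence
  struct_uid <- if (!is.null(ss) && length(ss) > 0L &&
                    !is.null(ss[[1L]]$ReferencedSOPInstanceUID)) {
    as.character(ss[[1L]]$ReferencedSOPInstanceUID)
  } else NA_character_
  tibble::tibble(
    instance_uid = uid,
    plan_label = as.character(attr_or(attrs, "RTPlanLabel", "")),
    fractions_planned = as.integer(nf),
    referenced_struct_uid = struct_uid
  )
}

#' Extract structure-set metadata from an instance attribute set
#'
#' Resolves the referenced planning-CT series UID by walking the referenced
#' frame-of-reference chain (frame of reference -> referenced study ->
#' referenced series).
#'
#' @param attrs Named list of DICOM attributes declaring the RT structure-set
#'   SOP class.
#' @return One-row tibble with columns `instance_uid` and
#'   `referenced_ct_series_uid` (`NA` when absent).
#' @export
extract_struct_meta <- function(attrs) {
  if (!identical(attrs$SOPClassUID, rt_sop_classes$STRUCTURE_SET)) {
    rlang::abort("attribute set does not declare the structure-set SOP class",
                 class = "rt_extract_error", attribute = "SOPClassUID")
  }
  uid <- require_attr(attrs, "SOPInstanceUID")
  ct_uid <- NA_character_
  frefs <- attrs$ReferencedFrameOfReferenceSequence
  if (!is.null(frefs) && length(frefs) > 0L) {
    studies <- frefs[[1L]]$RTReferencedStudySequence
    if (!is.null(studies) && length(studies) > 0L) {
      series <- studies[[1L]]$RTReferencedSeriesSequence
      if (!is.null(series) && length(series) > 0L &&
          !is.null(series[[1L]]$SeriesInstanceUID)) {
        ct_uid <- as.character(series[[1L]]$SeriesInstanceUID)
      }
    }
  }
  tibble::tibble(instance_uid = uid, referenced_ct_series_uid = ct_uid)
}

#' Walk the reference chain of one treatment record
#'
#' The four object kinds form a linked chain: the record references its plan,
#' the plan its structure set, the structure set its planning CT series. This
#' returns the chain of referenced objects in that order, truncated at the
#' first absent reference — truncation is a normal outcome, never an error.
#'
#' @param record One-row tibble from [extract_record_meta()].
#' @param plan_lookup Function mapping a plan UID to an
#'   [extract_plan_meta()] row, or `NULL` when the plan cannot be resolved.
#' @param struct_lookup Function mapping a structure-set UID to an
#'   [extract_struct_meta()] row, or `NULL`.
#' @return Tibble with columns `kind` (prefix of
#'   `PLAN`, `STRUCTURE_SET`, `CT_SERIES`) and `uid`.
#' @export
reference_chain <- function(record, plan_lookup, struct_lookup) {
  out <- tibble::tibble(kind = "PLAN", uid = record$referenced_plan_uid)
  plan <- plan_lookup(record$referenced_plan_uid)
  if (is.null(plan) || is.na(plan$referenced_struct_uid)) return(out)
  out <- dplyr::bind_rows(
    out, tibble::tibble(kind = "STRUCTURE_SET", uid = plan$referenced_struct_uid)
  )
  struct <- struct_lookup(plan$referenced_struct_uid)
  if (is.null(struct) || is.na(struct$referenced_ct_series_uid)) return(out)
  dplyr::bind_rows(
    out, tibble::tibble(kind = "CT_SERIES", uid = struct$referenced_ct_series_uid)
  )
}
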