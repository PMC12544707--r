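# Hand-built attribute sets and tiny stores used across the suite. These are
# deliberately independent of the clinic generator so extractor and store
# tests do not lean on the code they help to test elsewhere.

rec_fixture <- function(uid = "1.9.1", plan_uid = "1.9.5",
                        date = "20240502", fraction = 3L,
                        patient_id = "ZZ100001", patient_name = "ZZTEST^P001",
                        study_uid = "1.9.100", series_uid = "1.9.101",
                        study_date = "20240401", time = "081500",
                        physician = "ADAMS^A") {
  list(
    PatientID = patient_id, PatientName = patient_name,
    PatientBirthDate = "19500101", PhysiciansOfRecord = physician,
    StudyInstanceUID = study_uid, StudyDate = study_date,
    SeriesInstanceUID = series_uid, Modality = "RTRECORD",
    SOPClassUID = rt_sop_classes$TREATMENT_RECORD, SOPInstanceUID = uid,
    TreatmentDate = date, TreatmentTime = time,
    ReferencedRTPlanSequence = list(list(ReferencedSOPInstanceUID = plan_uid)),
    TreatmentSessionBeamSequence = list(
      list(CurrentFractionNumber = fraction),
      list(CurrentFractionNumber = fraction)
    )
  )
}

plan_fixture <- function(uid = "1.9.5", fractions = 25L,
                         struct_uid = "1.9.6", label = "TEST_PLAN",
                         patient_id = "ZZ100001", study_uid = "1.9.100",
                         series_uid = "1.9.102", study_date = "20240401") {
  attrs <- list(
    PatientID = patient_id, PatientName = "ZZTEST^P001",
    PatientBirthDate = "19500101",
    StudyInstanceUID = study_uid, StudyDate = study_date,
    SeriesInstanceUID = series_uid, Modality = "RTPLAN",
    SOPClassUID = rt_sop_classes$PLAN, SOPInstanceUID = uid,
    RTPlanLabel = label,
    FractionGroupSequence = list(list(NumberOfFractionsPlanned = fractions))
  )
  if (!is.null(struct_uid)) {
    attrs$ReferencedStructureSetSequence <-
      list(list(ReferencedSOPInstanceUID = struct_uid))
  }
  attrs
}

struct_fixture <- function(uid = "1.9.6", ct_series_uid = "1.9.7",
                           patient_id = "ZZ100001", study_uid = "1.9.100",
                           series_uid = "1.9.103", study_date = "20240401") {
  attrs <- list(
    PatientID = patient_id, PatientName = "ZZTEST^P001",
    PatientBirthDate = "19500101",
    StudyInstanceUID = study_uid, StudyDate = study_date,
    SeriesInstanceUID = series_uid, Modality = "RTSTRUCT",
    SOPClassUID = rt_sop_classes$STRUCTURE_SET, SOPInstanceUID = uid
  )
  if (!is.null(ct_series_uid)) {
    attrs$ReferencedFrameOfReferenceSequence <- list(list(
      RTReferencedStudySequence = list(list(
        RTReferencedSeriesSequence = list(list(
          SeriesInstanceUID = ct_series_uid))))))
  }
  attrs
}

ct_fixture <- function(uid = "1.9.8", ct_series_uid = "1.9.7",
                       patient_id = "ZZ100001", study_uid = "1.9.100",
                       study_date = "20240401") {
  list(
    PatientID = patient_id, PatientName = "ZZTEST^P001",
    PatientBirthDate = "19500101",
    StudyInstanceUID = study_uid, StudyDate = study_date,
    SeriesInstanceUID = ct_series_uid, Modality = "CT",
    SOPClassUID = rt_sop_classes$CT_IMAGE, SOPInstanceUID = uid
  )
}

# A store of known shape: n_patients x studies x series, one instance per
# series; returns the store and the ground-truth placement table.
grid_store <- function(n_patients = 3L, n_studies = 2L, n_series = 2L,
                       hierarchical_only = TRUE) {
  store <- dicom_store("grid", hierarchical_only = hierarchical_only)
  rows <- list()
  for (p in seq_len(n_patients)) {
    for (st in seq_len(n_studies)) {
      for (se in seq_len(n_series)) {
        path <- list(patient_id = sprintf("ZZ%06d", p),
                     study_uid = sprintf("1.5.%d.%d", p, st),
                     series_uid = sprintf("1.5.%d.%d.%d", p, st, se),
                     instance_uid = sprintf("1.5.%d.%d.%d.1", p, st, se))
        store_put(store, list(
          PatientID = path$patient_id, PatientName = sprintf("ZZTEST^P%03d", p),
          StudyInstanceUID = path$study_uid, StudyDate = "20240601",
          SeriesInstanceUID = path$series_uid, Modality = "CT",
          SOPClassUID = rt_sop_classes$CT_IMAGE,
          SOPInstanceUID = path$instance_uid
        ))
        rows[[length(rows) + 1L]] <- tibble::as_tibble(path)
      }
    }
  }
  list(store = store, placement = dplyr::bind_rows(rows))
}

# Independent brute-force path lookup over the exhaustive instance view.
brute_force_paths <- function(store, uid) {
  inst <- store_instances(store)
  inst[inst$instance_uid == uid,
       c("patient_id", "study_uid", "series_uid", "instance_uid")]
}

# A complete single-course store pair (source + archive) built by hand.
chain_stores <- function(archive_has = c("record", "plan", "struct", "ct")) {
  source <- dicom_store("src", hierarchical_only = FALSE)
  archive <- dicom_store("dst", hierarchical_only = TRUE)
  objs <- list(
    record = rec_fixture(),
    plan = plan_fixture(),
    struct = struct_fixture(),
    ct = ct_fixture()
  )
  for (a in objs) store_put(source, a)
  for (k in archive_has) store_put(archive, objs[[k]])
  list(source = source, archive = archive, objs = objs)
}
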