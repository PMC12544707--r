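# rtbackup

Incremental backup and disaster-recovery dashboards for DICOM-RT treatment
records.

Radiation oncology clinics depend on the record-and-verify (R&V) system to
know, for every patient, which plan is being delivered and which fraction
comes next. Ransomware attacks have taken R&V systems offline for days to
weeks, forcing clinics to reconstruct treatment state by hand before anyone
could be treated again. `rtbackup` is for the physicists and informatics
staff who want that state continuously mirrored somewhere an attack on the
R&V system cannot reach — an independent RT-PACS archive — and retrievable
as a simple roster when everything else is down.

The package implements three procedures:

* **Journaled incremental backup.** On a short cycle (default every
  10 minutes), query the R&V source for the day's RT treatment records
  (C-FIND analogue), skip those already journalled today, and transfer each
  new record (C-MOVE analogue) with a bounded retry budget — seven retries
  after the first attempt. Successes are appended to a per-day journal;
  exhausted failures go to a global failure log and are cleared
  automatically when a later cycle succeeds. `emit_daily_report()` turns a
  day's cycles into the operational summary a clinic would mail out
  nightly.
* **Reference closure.** Each record references its RT plan, the plan its
  structure set, the structure set its planning CT series
  (RTRECORD → RTPLAN → RTSTRUCT → CT). Because archives support only
  hierarchical querying, objects known by bare SOP instance UID are located
  by a deterministic breadth-first search over the
  Patient → Study → Series → Instance tree (`locate_instance()`). Every
  cycle audits the chain of each archived record and recovers missing links
  from the source systems, so the archive converges to referential
  completeness.
* **Recovery dashboard.** `build_dashboard()` reconstructs the on-treatment
  roster from the archive alone: records found via a study-date window two
  calendar months back, reduced per (patient, plan) to the most recent
  record, keeping courses that are incomplete and were treated within the
  past seven days. Output is a fixed-header CSV readable in any text
  viewer.

A deterministic synthetic-clinic generator (`generate_clinic()`) with a
ground-truth ledger makes the whole pipeline testable without any clinical
data, including injectable archive gaps and scripted transfer faults.

## Worked example

Simulate a small clinic (six patients, courses mid-flight, every treatment
record still un-archived and half the approved plans never pushed to the
archive), advance one treatment day, run a backup cycle, and build the
roster:

```r
library(rtbackup)

day0 <- as.Date("2024-06-28")
clinic <- generate_clinic(clinic_spec(
  n_patients = 6, as_of = day0,
  start_date_window = c(day0 - 30, day0 - 1),
  gap_rates = list(TREATMENT_RECORD = 1.0, PLAN = 0.5),
  seed = 7
))
clinic
#> <rt_clinic as of 2024-06-28> 6 patients, 9 courses, 127 delivered fractions

advance_day(clinic, day0 + 3)          # Monday's treatments hit the source
state <- backup_state(tempfile())
report <- run_cycle(clinic$source, clinic$archive, state, now = day0 + 3)
report
#> <backup cycle 2024-07-01> queried 8, new 8, succeeded 8, failed 0
```

Eight records were treated that Monday; all were new (none journalled yet)
and all transferred. The cycle's closure pass noticed that three of those
records referenced plans missing from the archive and recovered them from
the source:

```r
report$closure[c("kind", "status", "n_instances")]
#> # A tibble: 3 × 3
#>   kind  status  n_instances
#>   <chr> <chr>         <int>
#> 1 PLAN  SUCCESS           1
#> 2 PLAN  SUCCESS           1
#> 3 PLAN  SUCCESS           1
```

The disaster-mode roster comes from the archive only — the source handle is
never touched:

```r
rows <- build_dashboard(clinic$archive, day0 + 3)
write_dashboard(rows, "dash.csv")
```

```
PatientName,MRN,DOB,Physician,PlanLabel,FractionsPlanned,CurrentFraction,LastTreatmentDate
ZZTEST^P002,ZZ100002,1972-04-18,DIAZ^D,ZZ100002_PLAN1,30,21,2024-07-01
ZZTEST^P003,ZZ100003,1989-02-22,BAKER^B,ZZ100003_PLAN1,25,16,2024-07-01
ZZTEST^P003,ZZ100003,1989-02-22,BAKER^B,ZZ100003_PLAN2,34,13,2024-07-01
ZZTEST^P004,ZZ100004,1965-09-13,DIAZ^D,ZZ100004_PLAN1,15,12,2024-07-01
ZZTEST^P004,ZZ100004,1965-09-13,DIAZ^D,ZZ100004_PLAN2,21,6,2024-07-01
ZZTEST^P005,ZZ100005,1986-05-02,ADAMS^A,ZZ100005_PLAN2,16,6,2024-07-01
ZZTEST^P006,ZZ100006,1981-08-19,DIAZ^D,ZZ100006_PLAN1,32,20,2024-07-01
```

Each line is one plan of one currently treated patient: patient P003 is on
two concurrent plans (fraction 16 of 25 and 13 of 34, both treated today),
while the clinic's completed and long-finished courses are absent. The
`FractionsPlanned`/`CurrentFraction` pair is what a therapist needs to set
up the next session from the archive alone.

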