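---
title: "Methods: incremental DICOM-RT backup, reference closure, and the recovery dashboard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incremental DICOM-RT backup, reference closure, and the recovery dashboard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtbackup)
```

## The problem

External-beam radiotherapy is delivered in daily fractions over weeks, and
every delivered fraction is recorded by the record-and-verify (R&V) system as
a DICOM RT Treatment Record. When ransomware takes the R&V system offline, a
clinic that cannot answer "which patients are mid-course, on which plan, at
which fraction?" cannot safely resume treatment, and missed fractions carry a
real oncologic cost. `rtbackup` maintains a continuously updated copy of that
treatment state in an independent RT-PACS archive, keeps the archive
referentially complete, and can reconstruct an on-treatment roster from the
archive alone — the disaster-mode deliverable.

Three cooperating procedures do this work:

1. **Incremental journaled backup** (`run_cycle()`): a short cycle that
   queries the day's treatment records from the R&V source, skips those
   already archived today, transfers the rest with bounded retry, and
   reconciles a per-day journal and a global failure log.
2. **Reference closure** (`audit_record()`, `recover_missing()`): each
   treatment record references its plan; the plan references its structure
   set; the structure set references the planning CT series. Every cycle
   verifies this chain exists at the archive and recovers missing links from
   the source systems.
3. **Dashboard reconstruction** (`build_dashboard()`): a roster of currently
   treated patients computed purely from archived metadata, written as a CSV
   readable in any text viewer.

## The backup cycle and its failure model

A cycle is single-shot and idempotent; a scheduler (or `rbrdt_backup(once =
FALSE)`) provides the recurrence. The **journal** is a per-day, append-only
file of successfully archived record UIDs, written after every success, so a
crash between transfers loses nothing and a re-run never re-transfers a
record. The **failure log** is global and event-sourced (append-only
`failed` / `resolved` lines whose fold is the current state); a record that
exhausts its retries lands there and is removed automatically when a later
cycle archives it.

Transfer failure is a value, not an exception. Each new record is attempted
up to `1 + max_retries` times within the cycle, stopping at the first
success; `max_retries` defaults to 7, read as seven *retries* after the
initial attempt, eight attempts in total. Retries are immediate and
in-cycle rather than deferred to later cycles — a transient fault should not
cost a 10-minute cadence slot — while persistent faults are retried anyway
on later cycles through the failure-log/journal reconciliation. Records
treated near midnight but queried on the next calendar date cannot be
duplicated: a record absent from today's journal but already present at the
destination is journalled without a transfer.

The cycle interval defaults to **10 minutes**. A typical EBRT appointment
occupies 15–30 minutes, so a 10-minute cadence bounds the treatment data at
risk to less than one appointment while keeping query load trivial. The
day's record query filters by treatment *date* only: treatment-record
objects are not queryable by time, which is also why the dashboard's
recency logic works in whole days.

## Hierarchical location by breadth-first search

The archive supports only hierarchical querying: a series query needs the
patient and study identifiers, an instance query needs all three. But the
reference chain yields bare SOP instance UIDs. `locate_instance()` therefore
recovers the full Patient → Study → Series → Instance address by
breadth-first search: enumerate candidate patients, then their studies, then
their series, then probe each series with a UID-matched instance query
(probing, rather than listing every instance, halves the query volume).

Determinism and safety choices:

* The frontier is expanded in lexicographic identifier order, so searches
  are reproducible.
* The final level is always completed before answering. A UID found at two
  distinct paths — standard-violating, but observed in practice — raises a
  structured ambiguity error listing every path, because silently returning
  the first hit could resume a patient on the wrong object.
* A miss raises a not-found error carrying the number of nodes visited,
  which the tests use to prove the search was exhaustive and visited nothing
  twice.
* Optional hints (a known patient, say) prune the search to one subtree.
  The engine uses this: objects referenced by a record belong to that
  record's patient, so closure searches never leave the patient's subtree.

## Reference closure

`audit_record()` walks the chain RECORD → PLAN → STRUCTURE SET → CT SERIES,
truncating at the first absent *reference* (a plan without a structure-set
reference is a complete chain of one). Existence at the archive is checked
by live hierarchical location, not a cached index, so the audit remains
trustworthy after out-of-band archive changes. When a link is missing from
the archive but its metadata is needed to continue the walk, the metadata is
resolved from the configured source stores (R&V first, then any separate
planning system, in order). Recovery proceeds in chain order — a structure
set is never recovered before its referencing plan has been attempted — so a
partially recovered archive is always navigable top-down. CT is handled at
series granularity: treatment resumption needs the planning series, and
per-slice accounting adds nothing. An object absent from every source is
reported `UNRECOVERABLE` and the remaining links are still attempted.

Closure runs as part of every backup cycle for the records archived in that
cycle; `rbrdt_audit()` applies the same walk to the whole archive on demand.

## The on-treatment roster

A patient is *currently being treated* when they have not completed all
planned fractions and their most recent fraction was delivered within the
past **seven days** (chosen so a week-long treatment break does not hide a
patient, while long-finished courses drop off). The roster is built from the
archive alone:

1. **Candidate query**: a study-level query windowed on the study date (the
   simulation-CT creation date) spanning the **two calendar months** before
   the reference date — wide enough to include the longest conventional
   fractionation courses — then descent to the record instances of each
   admitted study.
2. **Per (patient, plan) reduction**: the most recent record by treatment
   date, then time, wins. Resolving "most recent" per plan rather than per
   patient is what lets a patient on two concurrent plans appear as two
   roster lines, grouped together.
3. **Filters**: a course whose current fraction has reached the plan's
   fraction count is complete and excluded; both window boundaries are
   inclusive (a last fraction exactly seven days old stays; a study exactly
   two months old is queried). "Two months" is calendar-month arithmetic
   with day clamping (`months_before()`: Mar 31 − 2 months = Jan 31).
   Recency compares dates only, never times, matching the date-only
   granularity of the record query.
4. **Degenerate inputs**: a record whose plan cannot be located in the
   archive keeps its roster row with `fractions_planned = NA` plus a
   warning — visibility over silent omission, since that row is exactly a
   patient whose resumption needs manual attention.

The CSV contract is a fixed eight-column header
(`PatientName,MRN,DOB,Physician,PlanLabel,FractionsPlanned,CurrentFraction,LastTreatmentDate`),
ISO-8601 dates, rows sorted by patient name, MRN, then plan label, so
identical archives produce byte-identical files. `PlanLabel` and
`LastTreatmentDate` extend the six identity/course fields because a roster
one cannot act on (which plan? how stale?) is not a recovery tool.

## Attribute mapping

DICOM-RT linkage is carried by standard sequences, and the extractors read
exactly those: record → plan through the referenced-plan sequence
(300C,0002); the delivered fraction as the maximum current-fraction number
(3008,0022) across the treated-beam session items (all beams of a session
share the session's fraction index, so the maximum is robust to partial
sessions); fractions planned from the fraction-group item (300A,0078); plan
→ structure set through (300C,0060); structure set → CT series through the
referenced frame-of-reference chain. Physician of record comes from
(0008,1048), falling back to the referring physician (0008,0090), else the
empty string. Dates use DICOM `DA` syntax and are compared as calendar
dates, never strings; times are fixed-width `TM` strings, where
lexicographic and chronological order coincide.

## The synthetic clinic generator

`generate_clinic()` emulates the population the tool serves: patients
carrying one or two EBRT courses of 5–35 fractions, treated on weekdays,
with the planning chain (CT series, structure set, plan) created a few days
before the course starts and one treatment record per delivered fraction.
Two failure mechanisms are injectable because they are the tool's reason to
exist: per-kind probabilities of omission from the archive (the imperfect
manual push of approved plans), and scripted transfer faults
(`fault_policy()`: fail the first *k* attempts per instance, fail always,
or refuse the association). Everything is deterministic given the spec and
seed; UIDs live under a reserved synthetic root and identities use an
unmistakably synthetic `ZZTEST^Pnnn` scheme.

The generator's ground-truth ledger — who was generated, with which
schedules, and which objects were omitted — is the independent oracle for
every end-to-end test: `roster_from_ledger()` derives the on-treatment
roster from the ledger with no store queries and no pipeline code, and
conservation checks compare archive contents against ledger totals.

What the generator does **not** model, and what passing tests therefore do
not show: image pixel data and dose content (objects are metadata stubs);
plan revisions or re-plans (one plan ↔ one structure set ↔ one CT series per
course); brachytherapy and non-EBRT records; vendor-specific attribute
quirks; concurrent mutation of the stores during a query; and real network
behaviour — the query/retrieve contract is exercised against in-memory
stores, so timeouts, association negotiation, and transfer-syntax issues
are out of scope. The contract tests are written against a store factory so
a network-backed implementation can be added and must pass the same suite.

## Verification sizes and numerical choices

The shipped tests run clinics of 4–12 patients; oracle-equivalence sweeps
use ten random clinics of 5 patients (≤ 200 instances each), and the
multi-day properties use 8-patient clinics simulated over 30 days with one
or two cycles per day — small enough to iterate on, large enough that every
code path (weekends, completed courses, multi-plan patients, gaps, faults)
is exercised. There is no floating-point numerics in the tool; the only
boundary arithmetic is calendar arithmetic, and both window boundaries are
inclusive by design, as stated above. Tie-breaks are everywhere
lexicographic (search order, report ordering) or chronological with the
fixed-width time string as the secondary key.

## Known limitations

* No DICOM network transport is bundled: the store contract plus the
  file-backed serialization stand where a C-FIND/C-MOVE SCU would; the
  configuration schema already carries the AE-title/host/port keys a
  network backend needs.
* The tool trusts the source's treatment-date attribute; a record carrying a
  wrong date is invisible to the day query (though still reachable by a
  later audit).
* Completion is judged per plan (`current_fraction ≥ fractions_planned`);
  fractions are never summed across plans, so a course continued under a
  revised plan appears as two independent lines.
* Journal rollover follows the local calendar date; deployments spanning
  time zones should pin one.
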