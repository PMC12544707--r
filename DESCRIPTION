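Package: rtbackup
Title: Incremental Backup and Recovery Dashboards for DICOM-RT Treatment Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orchestrates incremental, journaled backup of DICOM-RT treatment
    records from a record-and-verify source to an RT-PACS archive, recovers the
    full chain of referenced objects (plan, structure set, planning CT series)
    via breadth-first hierarchical query, and reconstructs an on-treatment
    patient roster from archived metadata alone so radiotherapy treatments can
    resume when the record-and-verify system is offline. Includes a
    deterministic synthetic clinic generator with a ground-truth ledger for
    testing every component without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
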