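Package: faersdispro
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for pharmacovigilance disproportionality
    analysis of FAERS-style spontaneous-report databases: reading the
    quarterly dollar-delimited ASCII tables (DEMO, DRUG, REAC, OUTC, THER,
    INDI, DELETED), report-level cleaning (case deduplication, deleted-case
    removal, chronology filtering), Primary-Suspect drug cohort
    construction, drug-event 2x2 contingency tables at the MedDRA PT and
    SOC levels, the four standard signal-detection statistics (reporting
    odds ratio, proportional reporting ratio, BCPNN information component,
    and the closed-form relative reporting ratio EBGM) with a joint
    all-four detection criterion, sex/age subgroup analyses, time-to-onset
    summaries, and a synthetic spontaneous-reporting generator with
    planted drug-event rate ratios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
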