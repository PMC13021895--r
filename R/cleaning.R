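# Sort key for PRIMARYID comparisons: numeric ids compare numerically; a
# non-numeric id is compared as a zero-padded string (and counted, so the
# caller can log it).
.pid_key <- function(primaryid, width = 24L) {
  num <- suppressWarnings(as.numeric(primaryid))
  key <- ifelse(is.na(num),
                formatC(primaryid, width = width, flag = "0"),
                formatC(num, width = width, format = "f", digits = 0,
                        flag = "0"))
  attr(key, "n_nonnumeric") <- sum(is.na(num))
  key
}

#' Deduplicate DEMO records by case
#'
#' FAERS cases accumulate versions; one record must be kept per `CASEID`.
#' For each case the record with the latest `FDA_DT` is retained; among
#' records sharing the latest `FDA_DT`, the one with the largest
#' `PRIMARYID` is kept (numeric comparison; a non-numeric id falls back to
#' zero-padded string order and is logged). The operation is idempotent and
#' preserves the input order of the surviving records.
#'
#' @param demo data.frame of DEMO records from [read_faers_table()] (needs
#'   `caseid`, `primaryid`, `fda_dt_date`).
#' @return the surviving records, one per `caseid`.
#' @export
deduplicate_demo <- function(demo) {
  if (nrow(demo) == 0L) return(demo)
  pid <- .pid_key(demo$primaryid)
  nn <- attr(pid, "n_nonnumeric")
  if (nn > 0L) message("deduplicate_demo: ", nn, " non-numeric PRIMARYID(s)")
  fda <- demo$fda_dt_date
  fda_key <- ifelse(is.na(fda), -Inf, as.numeric(fda))
  ord <- order(demo$caseid, fda_key, pid)
  last <- !duplicated(demo$caseid[ord], fromLast = TRUE)
  keep_rows <- sort(seq_len(nrow(demo))[ord][last])
  out <- demo[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove cases marked for deletion
#'
#' FAERS publishes the case ids of withdrawn reports; no surviving record
#' may carry one of them.
#'
#' @param demo data.frame with a `caseid` column.
#' @param deleted_caseids character vector of deleted case ids (or a DELETED
#'   records data.frame with a `caseid` column).
#' @return the records whose `caseid` is not deleted.
#' @export
remove_deleted <- function(demo, deleted_caseids) {
  if (is.data.frame(deleted_caseids)) {
    deleted_caseids <- deleted_caseids$caseid
  }
  deleted_caseids <- trimws(as.character(deleted_caseids))
  out <- demo[!(demo$caseid %in% deleted_caseids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble cleaned tables into a report store
#'
#' Joins the per-table records into a single `faers_reports` object: one
#' DEMO row per report plus the drug, reaction and outcome rows restricted
#' to the surviving reports. Reaction rows keep the verbatim PT (whitespace
#' normalized). When a THER table is supplied, therapy start dates are
#' merged onto drug rows by (`primaryid`, `drug_seq`) wherever the drug row
#' itself has none.
#'
#' @param demo,drug,reac parsed record data.frames ([read_faers_table()]).
#' @param outc,ther optional parsed OUTC / THER records.
#' @return an object of class `faers_reports` with elements `demo`,
#'   `drugs`, `reactions`, `outcomes`.
#' @export
assemble_reports <- function(demo, drug, reac, outc = NULL, ther = NULL) {
  ids <- demo$primaryid
  if (anyDuplicated(ids)) stop("duplicate primaryid in DEMO; deduplicate first")
  drugs <- drug[drug$primaryid %in% ids, , drop = FALSE]
  if (!is.null(ther) && nrow(ther) > 0L) {
    need <- !nzchar(drugs$start_dt)
    key_d <- paste(drugs$primaryid, drugs$drug_seq, sep = "\r")
    key_t <- paste(ther$primaryid, ther$drug_seq, sep = "\r")
    hit <- match(key_d, key_t)
    take <- need & !is.na(hit)
    if (any(take)) {
      drugs$start_dt[take] <- ther$start_dt[hit[take]]
      drugs$start_dt_prec[take] <- ther$start_dt_prec[hit[take]]
      drugs$start_dt_date[take] <- ther$start_dt_date[hit[take]]
    }
  }
  reactions <- reac[reac$primaryid %in% ids, , drop = FALSE]
  outcomes <- if (is.null(outc)) {
    data.frame(primaryid = character(0), outcome_code = character(0),
               stringsAsFactors = FALSE)
  } else {
    outc[outc$primaryid %in% ids, , drop = FALSE]
  }
  rownames(drugs) <- rownames(reactions) <- rownames(outcomes) <- NULL
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 outcomes = outcomes),
            class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports>", nrow(x$demo), "report(s),", nrow(x$drugs),
      "drug row(s),", nrow(x$reactions), "reaction row(s)\n")
  invisible(x)
}

# Subset a faers_reports object to a set of primaryids, preserving order.
.subset_reports <- function(reports, ids) {
  keep <- reports$demo$primaryid %in% ids
  demo <- reports$demo[keep, , drop = FALSE]
  rownames(demo) <- NULL
  assemble_reports(demo, reports$drugs, reports$reactions, reports$outcomes)
}

#' Drop chronologically inconsistent reports
#'
#' A report is excluded when a drug start date lies strictly after the
#' event onset date (both at day precision; partial dates are not evaluable
#' and do not trigger exclusion here — the time-to-onset module handles
#' them), or when its FDA receipt date is missing or unparseable, the one
#' date every analysis requires. Each dropped report carries a reason code;
#' the kept and dropped sets partition the input.
#'
#' @param reports a `faers_reports` object.
#' @return list with `kept` (a `faers_reports`) and `dropped` (data.frame
#'   `primaryid`, `reason` with reasons `"missing_fda_dt"` /
#'   `"chronology"`).
#' @export
chronology_filter <- function(reports) {
  demo <- reports$demo
  bad_fda <- demo$fda_dt_prec != "day"

  ev_idx <- match(reports$drugs$primaryid, demo$primaryid)
  ev_date <- demo$event_dt_date[ev_idx]
  ev_day <- demo$event_dt_prec[ev_idx] == "day"
  st_day <- reports$drugs$start_dt_prec == "day"
  conflict <- st_day & ev_day &
    !is.na(reports$drugs$start_dt_date) & !is.na(ev_date) &
    reports$drugs$start_dt_date > ev_date
  bad_chrono <- demo$primaryid %in% reports$drugs$primaryid[conflict]

  reason <- ifelse(bad_fda, "missing_fda_dt",
                   ifelse(bad_chrono, "chronology", NA_character_))
  dropped <- data.frame(primaryid = demo$primaryid[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  kept <- .subset_reports(reports, demo$primaryid[is.na(reason)])
  list(kept = kept, dropped = dropped)
}

#' Build a Primary-Suspect drug cohort
#'
#' A report joins the cohort when at least one of its drug records matches
#' the lexicon ([lexicon_match()]) *and* that record carries the Primary
#' Suspect (PS) role code. Other suspect drugs on the report are permitted
#' by default; `strict_single_suspect` additionally requires that every
#' suspect-role (PS/SS) record on the report matches the lexicon.
#'
#' @param reports a `faers_reports` object (cleaned).
#' @param lexicon a [drug_lexicon()].
#' @param strict_single_suspect logical; see above.
#' @return an object of class `cohort`: list with `label` and `report_ids`.
#' @export
build_cohort <- function(reports, lexicon, strict_single_suspect = FALSE) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  d <- reports$drugs
  m <- lexicon_match(d$drug_name, d$prod_ai, lexicon)
  ids <- unique(d$primaryid[m & d$role_code == "PS"])
  if (strict_single_suspect) {
    foreign <- unique(d$primaryid[!m & d$role_code %in% c("PS", "SS")])
    ids <- setdiff(ids, foreign)
  }
  structure(list(label = lexicon$target_label,
                 report_ids = ids),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", x$label, "-", length(x$report_ids), "report(s)\n")
  invisible(x)
}

#' Run the full report-level cleaning pipeline
#'
#' Applies the cleaning steps in their standard order — case deduplication,
#' deleted-case removal, report assembly, chronology filtering — and
#' records the in/out counts of every step in a manifest.
#'
#' @param demo,drug,reac parsed record data.frames.
#' @param outc,ther optional parsed records.
#' @param deleted optional DELETED records (or character vector of caseids).
#' @return list with `reports` (a `faers_reports`) and `manifest` (a
#'   data.frame of step, n_in, n_out, n_dropped) plus `dropped` reasons.
#' @export
clean_reports <- function(demo, drug, reac, outc = NULL, ther = NULL,
                          deleted = NULL) {
  n0 <- nrow(demo)
  demo1 <- deduplicate_demo(demo)
  n1 <- nrow(demo1)
  demo2 <- if (is.null(deleted)) demo1 else remove_deleted(demo1, deleted)
  n2 <- nrow(demo2)
  reports <- assemble_reports(demo2, drug, reac, outc, ther)
  chrono <- chronology_filter(reports)
  n3 <- nrow(chrono$kept$demo)
  manifest <- data.frame(
    step = c("deduplicate", "remove_deleted", "chronology_filter"),
    n_in = c(n0, n1, n2),
    n_out = c(n1, n2, n3),
    n_dropped = c(n0 - n1, n1 - n2, n2 - n3),
    stringsAsFactors = FALSE
  )
  list(reports = chrono$kept, manifest = manifest, dropped = chrono$dropped)
}
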