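#' Build drug-event 2x2 contingency tables
#'
#' For every event observed at the chosen MedDRA level, the four cells of
#' the standard pharmacovigilance 2x2 table are computed against the
#' all-other-reports background: `a` cohort reports with the event, `b`
#' cohort reports without it, `c` non-cohort reports with it, `d` the rest.
#' The counting unit is the report: a PT repeated within one report counts
#' once, and at SOC level a report counts once toward a SOC when at least
#' one of its PTs maps there (PTs missing from the mapping are tallied and
#' excluded). At PT level, events with `a < min_count` are dropped before
#' any statistic is computed; no count filter applies at SOC level.
#'
#' @param reports a `faers_reports` object (cleaned database).
#' @param cohort a [build_cohort()] result, or a character vector of
#'   `primaryid`s.
#' @param level `"PT"` or `"SOC"`.
#' @param soc_map a [soc_mapping()]; required when `level = "SOC"`.
#' @param min_count minimum `a` at PT level (default 3).
#' @param row_level count raw reaction rows instead of distinct reports
#'   (off by default; provided for sensitivity analyses only).
#' @return an object of class `event_table_set`: a data.frame with columns
#'   `event`, `a`, `b`, `c`, `d` and attributes `drug_label`, `level`,
#'   `n_cohort`, `n_total`, `n_unmapped_pts`, `min_count`.
#' @export
build_tables <- function(reports, cohort, level = c("PT", "SOC"),
                         soc_map = NULL, min_count = 3, row_level = FALSE) {
  level <- match.arg(level)
  label <- "cohort"
  if (inherits(cohort, "cohort")) {
    label <- cohort$label
    cohort <- cohort$report_ids
  }
  all_ids <- reports$demo$primaryid
  if (!all(cohort %in% all_ids)) {
    stop("cohort contains primaryid(s) absent from the cleaned reports")
  }
  n_total <- length(all_ids)
  n_cohort <- length(unique(cohort))

  ev <- data.frame(primaryid = reports$reactions$primaryid,
                   event = reports$reactions$pt,
                   stringsAsFactors = FALSE)
  n_unmapped <- 0L
  if (level == "SOC") {
    if (is.null(soc_map)) stop("level='SOC' requires a soc_map")
    upt <- unique(ev$event)
    socs <- soc_lookup(soc_map, upt)
    n_per <- lengths(socs)
    n_unmapped <- sum(n_per == 0L)
    idx <- match(ev$event, upt)
    rep_idx <- rep(seq_len(nrow(ev)), n_per[idx])
    ev <- data.frame(primaryid = ev$primaryid[rep_idx],
                     event = unlist(socs[idx], use.names = FALSE),
                     stringsAsFactors = FALSE)
  }
  if (!row_level) {
    ev <- ev[!duplicated(paste(ev$primaryid, ev$event, sep = "\r")), ,
             drop = FALSE]
  }

  in_cohort <- ev$primaryid %in% cohort
  events <- sort(unique(ev$event))
  fac <- factor(ev$event, levels = events)
  a <- as.integer(tapply(in_cohort, fac, sum, default = 0L))
  ac <- as.integer(table(fac))
  cc <- ac - a
  tab <- data.frame(event = events, a = a, b = n_cohort - a, c = cc,
                    d = n_total - n_cohort - cc, stringsAsFactors = FALSE)
  if (level == "PT" && min_count > 0) {
    tab <- tab[tab$a >= min_count, , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(tab, class = c("event_table_set", "data.frame"),
            drug_label = label, level = level, n_cohort = n_cohort,
            n_total = n_total, n_unmapped_pts = n_unmapped,
            min_count = min_count)
}

#' Project a table set onto its margin counts
#'
#' @param table_set an `event_table_set`.
#' @return data.frame with `event`, `a`, `n_drug` (= a+b), `n_event`
#'   (= a+c), `N`.
#' @export
summarize_counts <- function(table_set) {
  data.frame(event = table_set$event,
             a = table_set$a,
             n_drug = table_set$a + table_set$b,
             n_event = table_set$a + table_set$c,
             N = table_set$a + table_set$b + table_set$c + table_set$d,
             stringsAsFactors = FALSE)
}
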