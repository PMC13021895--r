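#' Time-to-onset of a drug-event pair
#'
#' The onset interval is the difference in whole days between the event
#' date (`EVENT_DT`) and the drug start date (`START_DT`). A record is
#' excluded with a status code following the standard exclusion order:
#' `missing_date` when either date is absent; `negative_interval` when both
#' dates have day precision and the event precedes the start;
#' `invalid_date` when either date is partial (month/year precision) or
#' unparseable, so the interval cannot be computed; `extreme_interval` when
#' the interval exceeds `max_days` (a data-entry-error guard). Same-day
#' onset (0 days) is valid.
#'
#' @param start,event character vectors of raw date strings, or data.frames
#'   from [parse_faers_date()].
#' @param max_days longest plausible onset interval in days (default 3650).
#' @return data.frame with `days` (integer, `NA` unless valid) and `status`
#'   (`valid`, `missing_date`, `negative_interval`, `invalid_date`,
#'   `extreme_interval`).
#' @export
compute_tto <- function(start, event, max_days = 3650) {
  if (!is.data.frame(start)) start <- parse_faers_date(start)
  if (!is.data.frame(event)) event <- parse_faers_date(event)
  n <- nrow(start)
  stopifnot(nrow(event) == n)
  status <- rep("valid", n)
  days <- rep(NA_integer_, n)

  missing <- start$precision == "missing" | event$precision == "missing"
  both_day <- start$precision == "day" & event$precision == "day"
  dd <- as.integer(event$date - start$date)
  negative <- both_day & dd < 0
  partial <- !both_day & !missing
  extreme <- both_day & !is.na(dd) & dd >= 0 & dd > max_days

  status[extreme] <- "extreme_interval"
  status[partial] <- "invalid_date"
  status[negative] <- "negative_interval"
  status[missing] <- "missing_date"
  ok <- status == "valid"
  days[ok] <- dd[ok]
  data.frame(days = days, status = status, stringsAsFactors = FALSE)
}

#' Time-to-onset records for a drug cohort
#'
#' For every cohort report, the start date of the cohort drug is paired
#' with the report's event onset date. When the drug appears on several
#' rows, the earliest day-precision start is used; if none has day
#' precision, any non-empty partial start stands in (and is classified
#' `invalid_date`); a report with no recorded start at all is
#' `missing_date`.
#'
#' @param reports a `faers_reports` object.
#' @param lexicon the cohort's [drug_lexicon()] (identifies which drug rows
#'   carry the relevant start date).
#' @param cohort a `cohort` or `primaryid` vector.
#' @param max_days passed to [compute_tto()].
#' @return data.frame with `primaryid`, `days`, `status`, one row per
#'   cohort report.
#' @export
cohort_tto <- function(reports, lexicon, cohort, max_days = 3650) {
  ids <- if (inherits(cohort, "cohort")) cohort$report_ids else cohort
  demo <- reports$demo[reports$demo$primaryid %in% ids, , drop = FALSE]
  d <- reports$drugs
  d <- d[d$primaryid %in% ids &
           lexicon_match(d$drug_name, d$prod_ai, lexicon), , drop = FALSE]

  # rank starts: day precision sorts first by date, then partial, then none
  day <- d$start_dt_prec == "day"
  rank <- ifelse(day, as.numeric(d$start_dt_date),
                 ifelse(nzchar(d$start_dt), 1e10, 2e10))
  ord <- order(d$primaryid, rank)
  first <- !duplicated(d$primaryid[ord])
  best <- d[ord, , drop = FALSE][first, , drop = FALSE]
  idx <- match(demo$primaryid, best$primaryid)
  start_text <- ifelse(is.na(idx), "", best$start_dt[idx])

  tto <- compute_tto(start_text, demo$event_dt, max_days = max_days)
  data.frame(primaryid = demo$primaryid, days = tto$days,
             status = tto$status, stringsAsFactors = FALSE)
}

#' Summarize time-to-onset records
#'
#' Median and quartiles (linear interpolation between order statistics,
#' `stats::quantile` type 7) over valid intervals, and counts/shares in the
#' conventional onset bins 0-7, >7-28, >28-60 and >60 days (first bin
#' closed on both ends; later edges upper-inclusive, so every nonnegative
#' day count falls in exactly one bin).
#'
#' @param tto data.frame from [compute_tto()] / [cohort_tto()], or an
#'   integer vector of valid day counts.
#' @return list with `n_valid`, `n_unknown`, `median`, `q1`, `q3` and
#'   `bins` (data.frame of bin, n, pct-of-valid).
#' @export
summarize_tto <- function(tto) {
  if (is.data.frame(tto)) {
    days <- tto$days[tto$status == "valid"]
    n_unknown <- sum(tto$status != "valid")
  } else {
    days <- tto[!is.na(tto)]
    n_unknown <- sum(is.na(tto))
  }
  n_valid <- length(days)
  bins_def <- c("0-7", "7-28", "28-60", ">=60")
  if (n_valid == 0L) {
    return(list(n_valid = 0L, n_unknown = n_unknown,
                median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                bins = data.frame(bin = bins_def, n = 0L, pct = NA_real_,
                                  stringsAsFactors = FALSE)))
  }
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  cutbin <- cut(days, breaks = c(-0.5, 7, 28, 60, Inf), labels = bins_def)
  tab <- table(cutbin)
  list(n_valid = n_valid, n_unknown = n_unknown,
       median = q[2], q1 = q[1], q3 = q[3],
       bins = data.frame(bin = bins_def, n = as.integer(tab),
                         pct = round(100 * as.integer(tab) / n_valid, 2),
                         stringsAsFactors = FALSE))
}
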