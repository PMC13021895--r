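#' Define a sex/age stratum
#'
#' Subgroups are defined by sex (`"F"`, `"M"`, `"unknown"`, `"any"`) and an
#' age group relative to a cut in years (default 60): `"under60"` means age
#' < cut, `"over_or_equal_60"` age >= cut, `"unknown"` missing or
#' unparseable age, `"any"` no restriction. Given the cut, the three age
#' groups partition every report set.
#'
#' @param sex one of `"F"`, `"M"`, `"unknown"`, `"any"`.
#' @param age_group one of `"under60"`, `"over_or_equal_60"`, `"unknown"`,
#'   `"any"`.
#' @param age_cut age cut in years.
#' @return an object of class `stratum_spec`.
#' @export
stratum_spec <- function(sex = "any", age_group = "any", age_cut = 60) {
  sex <- match.arg(sex, c("any", "F", "M", "unknown"))
  age_group <- match.arg(age_group,
                         c("any", "under60", "over_or_equal_60", "unknown"))
  structure(list(sex = sex, age_group = age_group, age_cut = age_cut),
            class = "stratum_spec")
}

# Age-group label per report given a cut.
.age_group_of <- function(age_years, cut) {
  ifelse(is.na(age_years), "unknown",
         ifelse(age_years < cut, "under60", "over_or_equal_60"))
}

#' Restrict a report store to a stratum
#'
#' @param reports a `faers_reports` object.
#' @param stratum a [stratum_spec()].
#' @return the reports whose demographics fall in the stratum.
#' @export
filter_stratum <- function(reports, stratum) {
  stopifnot(inherits(stratum, "stratum_spec"))
  demo <- reports$demo
  keep <- rep(TRUE, nrow(demo))
  if (stratum$sex != "any") keep <- keep & demo$sex == stratum$sex
  if (stratum$age_group != "any") {
    keep <- keep &
      .age_group_of(demo$age_years, stratum$age_cut) == stratum$age_group
  }
  .subset_reports(reports, demo$primaryid[keep])
}

#' Run a stratified signal analysis
#'
#' Restricts *both* the cohort and the background to the stratum — the
#' standard subgroup-disproportionality convention — then rebuilds the
#' contingency tables (the `min_count` filter re-applies within the
#' stratum) and recomputes all statistics. With `restrict_background =
#' FALSE` only the cohort is restricted and the background keeps every
#' stratum.
#'
#' @param reports a `faers_reports` object (cleaned database).
#' @param cohort a `cohort` or character vector of `primaryid`s.
#' @param stratum a [stratum_spec()].
#' @param restrict_background restrict the comparator reports to the
#'   stratum too (default `TRUE`).
#' @inheritParams build_tables
#' @inheritParams signal_stats
#' @return list with `tables` (an `event_table_set`) and `signals` (a
#'   [signal_stats()] data.frame). An empty stratum cohort yields empty
#'   tables with a warning.
#' @export
run_subgroup <- function(reports, cohort, stratum, level = c("PT", "SOC"),
                         soc_map = NULL, min_count = 3,
                         thresholds = default_thresholds(),
                         priors = bcpnn_priors(),
                         restrict_background = TRUE) {
  level <- match.arg(level)
  label <- if (inherits(cohort, "cohort")) cohort$label else "cohort"
  ids <- if (inherits(cohort, "cohort")) cohort$report_ids else cohort
  sub <- if (restrict_background) filter_stratum(reports, stratum) else reports
  sub_cohort_ids <- intersect(ids, filter_stratum(reports,
                                                  stratum)$demo$primaryid)
  if (length(sub_cohort_ids) == 0L) {
    warning("empty cohort in stratum (sex=", stratum$sex, ", age=",
            stratum$age_group, ")")
  }
  cohort_obj <- structure(list(label = label, report_ids = sub_cohort_ids),
                          class = "cohort")
  tables <- build_tables(sub, cohort_obj, level = level, soc_map = soc_map,
                         min_count = min_count)
  list(tables = tables,
       signals = signal_stats(tables, thresholds = thresholds,
                              priors = priors))
}

# counts + shares of one categorical vector, descending by count
.cat_summary <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "Unknown"
  tab <- sort(table(x), decreasing = TRUE)
  data.frame(category = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / length(x), 2),
             stringsAsFactors = FALSE)
}

#' Summarize the demographics of a cohort
#'
#' Produces the usual epidemiological-characteristics breakdown of a
#' spontaneous-report cohort: counts and percentages by sex, age group,
#' reporter occupation, outcome, country, route and FDA-receipt year, and
#' median/quartiles for age (years) and weight (kg) over non-missing
#' values. Demographic blocks sum to the cohort size; outcomes and routes,
#' which are report-level sets, count each distinct code once per report,
#' so those blocks can exceed it.
#'
#' @param reports a `faers_reports` object.
#' @param cohort optional `cohort` or `primaryid` vector; default all
#'   reports.
#' @param age_cut age cut in years for the age groups.
#' @return a named list of data.frames (`sex`, `age_group`, `reporter`,
#'   `outcome`, `country`, `route`, `year`) plus `age_summary` and
#'   `weight_summary` (n, median, q1, q3) and `n_reports`.
#' @export
summarize_demographics <- function(reports, cohort = NULL, age_cut = 60) {
  demo <- reports$demo
  if (!is.null(cohort)) {
    ids <- if (inherits(cohort, "cohort")) cohort$report_ids else cohort
    demo <- demo[demo$primaryid %in% ids, , drop = FALSE]
  }
  n <- nrow(demo)
  num_summary <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      return(data.frame(n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
  }
  per_report <- function(tbl, col) {
    t2 <- tbl[tbl$primaryid %in% demo$primaryid, , drop = FALSE]
    t2 <- t2[!duplicated(paste(t2$primaryid, t2[[col]], sep = "\r")), ,
             drop = FALSE]
    t2[[col]]
  }
  list(
    n_reports = n,
    sex = .cat_summary(demo$sex),
    age_group = .cat_summary(.age_group_of(demo$age_years, age_cut)),
    reporter = .cat_summary(demo$occp_cod),
    country = .cat_summary(demo$country),
    route = .cat_summary(per_report(reports$drugs, "route")),
    outcome = .cat_summary(per_report(reports$outcomes, "outcome_code")),
    year = .cat_summary(substr(demo$fda_dt, 1, 4)),
    age_summary = num_summary(demo$age_years),
    weight_summary = num_summary(demo$weight_kg)
  )
}
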