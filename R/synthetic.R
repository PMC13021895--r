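#' Specify a synthetic spontaneous-reporting database
#'
#' Defines the full generative model for a FAERS-format fake database with
#' known ground truth. Each report is assigned one Primary-Suspect drug
#' from the prevalence mixture (probability mass not claimed by the
#' configured drugs is split across `n_background_drugs` anonymous
#' background drugs). Each MedDRA PT is an independent per-report coin with
#' probability `p0 * RR(drug, pt)` capped at 1, where the planted rate
#' ratios come from `effects` and default to 1. Reports that draw zero
#' events are redrawn (capped retries, then one forced background event, so
#' every report is analyzable). Duplicate reports are exact clones with a
#' fresh `PRIMARYID` and a later `FDA_DT` (exercising the deduplication tie
#' rules deterministically); deleted cases are listed in a DELETED table.
#' Dates, demographics and onset intervals are drawn per the remaining
#' parameters. The same seed always reproduces the same database.
#'
#' @param seed integer RNG seed.
#' @param n_reports number of base reports (before duplication).
#' @param drugs data.frame with `label` and `prevalence` (summing to <= 1).
#' @param pts data.frame with `pt`, `soc`, `p0` (background per-report
#'   reporting probability).
#' @param effects optional data.frame with `drug`, `pt`, `rr` (rate ratio
#'   >= 0) for the planted associations.
#' @param n_background_drugs background drugs sharing the leftover
#'   prevalence mass.
#' @param duplicate_rate fraction of reports cloned as duplicates.
#' @param deleted_rate fraction of cases listed for deletion.
#' @param missing_event_dt_rate fraction of reports with no event date.
#' @param partial_date_rate fraction of drug start dates truncated to
#'   month precision.
#' @param dup_reaction_rate fraction of reaction rows duplicated verbatim
#'   (exercises report-level event counting).
#' @param concomitant_rate fraction of reports with an extra
#'   concomitant-role background drug row.
#' @param sex_split named probabilities for `F`, `M`, `unknown`.
#' @param age_unknown_rate fraction of reports with no usable age.
#' @param age_ranges data.frame with `weight`, `min`, `max` (uniform
#'   mixture over years, given age known).
#' @param tto_mean_days mean of the geometric onset-interval distribution.
#' @param date_range character length-2, YYYYMMDD bounds for start dates.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_reports = 10000L,
                             drugs = data.frame(label = "DRUG_A",
                                                prevalence = 0.1),
                             pts = default_pt_panel(),
                             effects = NULL,
                             n_background_drugs = 5L,
                             duplicate_rate = 0.05,
                             deleted_rate = 0.01,
                             missing_event_dt_rate = 0.23,
                             partial_date_rate = 0.05,
                             dup_reaction_rate = 0.02,
                             concomitant_rate = 0.3,
                             sex_split = c(F = 0.55, M = 0.37,
                                           unknown = 0.08),
                             age_unknown_rate = 0.23,
                             age_ranges = data.frame(
                               weight = c(0.62, 0.38),
                               min = c(18, 60), max = c(59, 90)),
                             tto_mean_days = 10,
                             date_range = c("20040701", "20240930")) {
  stopifnot(is.data.frame(drugs), all(c("label", "prevalence") %in%
                                        names(drugs)),
            is.data.frame(pts), all(c("pt", "soc", "p0") %in% names(pts)))
  if (any(drugs$prevalence < 0) || sum(drugs$prevalence) > 1 + 1e-12) {
    stop("drug prevalences must be nonnegative and sum to <= 1")
  }
  if (any(pts$p0 < 0 | pts$p0 > 1)) stop("pt probabilities must be in [0,1]")
  if (anyDuplicated(drugs$label) || anyDuplicated(pts$pt)) {
    stop("drug labels and pt names must be unique")
  }
  if (!is.null(effects)) {
    stopifnot(all(c("drug", "pt", "rr") %in% names(effects)))
    if (!all(effects$drug %in% drugs$label)) {
      stop("effects reference unconfigured drug(s)")
    }
    if (!all(effects$pt %in% pts$pt)) {
      stop("effects reference unconfigured pt(s)")
    }
    if (any(effects$rr < 0)) stop("rate ratios must be >= 0")
  }
  rates <- c(duplicate_rate, deleted_rate, missing_event_dt_rate,
             partial_date_rate, dup_reaction_rate, concomitant_rate,
             age_unknown_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  if (sum(pts$p0) <= 0) stop("infeasible config: all event probabilities 0")
  structure(list(seed = as.integer(seed), n_reports = as.integer(n_reports),
                 drugs = drugs, pts = pts, effects = effects,
                 n_background_drugs = as.integer(n_background_drugs),
                 duplicate_rate = duplicate_rate,
                 deleted_rate = deleted_rate,
                 missing_event_dt_rate = missing_event_dt_rate,
                 partial_date_rate = partial_date_rate,
                 dup_reaction_rate = dup_reaction_rate,
                 concomitant_rate = concomitant_rate,
                 sex_split = sex_split,
                 age_unknown_rate = age_unknown_rate,
                 age_ranges = age_ranges,
                 tto_mean_days = tto_mean_days,
                 date_range = date_range),
            class = "synthetic_config")
}

#' A small default panel of Preferred Terms
#'
#' Twelve PTs across five System Organ Classes with background reporting
#' probabilities shaped like the event mix of an antibiotic safety profile.
#' The probabilities sum to about 1.4, so a typical report lists one to
#' three events — as real spontaneous reports do — and the zero-event
#' redraw in [generate_faers()] is rarely triggered (keeping observed
#' disproportionality close to the planted values). Used as the default
#' `pts` argument of [synthetic_config()].
#'
#' @return data.frame with `pt`, `soc`, `p0`.
#' @export
default_pt_panel <- function() {
  data.frame(
    pt = c("Urticaria", "Rash", "Pruritus", "Angioedema",
           "Anaphylactic shock", "Type I hypersensitivity",
           "Drug-induced liver injury", "Cholestatic hepatitis",
           "Diarrhoea", "Nausea", "Vomiting", "Headache"),
    soc = c(rep("Skin and subcutaneous tissue disorders", 3),
            "Skin and subcutaneous tissue disorders",
            rep("Immune system disorders", 2),
            rep("Hepatobiliary disorders", 2),
            rep("Gastrointestinal disorders", 3),
            "Nervous system disorders"),
    p0 = c(0.2, 0.18, 0.12, 0.04, 0.02, 0.005,
           0.015, 0.005, 0.3, 0.25, 0.15, 0.12),
    stringsAsFactors = FALSE
  )
}


# format dates to YYYYMMDD via their unique values (far fewer strftime calls)
.fmt_ymd <- function(d) {
  ud <- unique(d)
  format(ud, "%Y%m%d")[match(d, ud)]
}
# Drug labels and prevalence vector including background drugs.
.drug_mixture <- function(config) {
  labels <- config$drugs$label
  prev <- config$drugs$prevalence
  rest <- 1 - sum(prev)
  nb <- config$n_background_drugs
  if (rest > 1e-12 && nb > 0L) {
    labels <- c(labels, sprintf("BACKGROUND_%02d", seq_len(nb)))
    prev <- c(prev, rep(rest / nb, nb))
  } else if (rest > 1e-12) {
    stop("prevalences sum to < 1 but n_background_drugs = 0")
  }
  data.frame(label = labels, prevalence = prev, stringsAsFactors = FALSE)
}

#' Ground truth of a synthetic configuration
#'
#' One row per (drug, PT) pair over every drug in the mixture (configured
#' and background) and every configured PT, with the planted rate ratio
#' (1 where no effect is configured), the capped per-report event
#' probability, the analytically induced odds ratio versus a
#' background-rate comparator, and the expected cohort event count
#' `E[a] = n * prevalence * min(1, RR * p0)`.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with `drug`, `pt`, `rr`, `prevalence`, `p0`,
#'   `p_event`, `induced_or`, `expected_a`.
#' @export
truth_table <- function(config) {
  mix <- .drug_mixture(config)
  grid <- expand.grid(drug = mix$label, pt = config$pts$pt,
                      stringsAsFactors = FALSE)
  grid$rr <- 1
  if (!is.null(config$effects)) {
    key <- paste(grid$drug, grid$pt, sep = "\r")
    ekey <- paste(config$effects$drug, config$effects$pt, sep = "\r")
    hit <- match(key, ekey)
    grid$rr[!is.na(hit)] <- config$effects$rr[hit[!is.na(hit)]]
  }
  grid$prevalence <- mix$prevalence[match(grid$drug, mix$label)]
  grid$p0 <- config$pts$p0[match(grid$pt, config$pts$pt)]
  grid$p_event <- pmin(1, grid$rr * grid$p0)
  grid$induced_or <- (grid$p_event / (1 - grid$p_event)) /
    (grid$p0 / (1 - grid$p0))
  grid$expected_a <- config$n_reports * grid$prevalence * grid$p_event
  grid
}

#' Generate a synthetic FAERS-format database
#'
#' Draws a complete table set (DEMO, DRUG, REAC, OUTC, THER, DELETED) under
#' a [synthetic_config()], together with its [truth_table()]. Deterministic
#' given the config (the seed is set internally); when `dir` is given, the
#' tables are also written as `$`-delimited ASCII files plus a
#' `truth.csv`, byte-identical across runs.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory (created if needed).
#' @return list with `tables` (named list of raw character data.frames with
#'   FAERS column names), `truth`, `config`, and `paths` when `dir` was
#'   given.
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  mix <- .drug_mixture(config)
  pts <- config$pts
  K <- nrow(pts)
  D <- nrow(mix)

  if (n == 0L) {
    empty <- function(cols) {
      as.data.frame(matrix(character(0), 0, length(cols),
                           dimnames = list(NULL, cols)),
                    stringsAsFactors = FALSE)
    }
    tables <- list(
      DEMO = empty(names(.faers_out_cols$DEMO)),
      DRUG = empty(names(.faers_out_cols$DRUG)),
      REAC = empty(names(.faers_out_cols$REAC)),
      OUTC = empty(names(.faers_out_cols$OUTC)),
      THER = empty(names(.faers_out_cols$THER)),
      DELETED = empty(names(.faers_out_cols$DELETED))
    )
    out <- list(tables = tables, truth = truth_table(config),
                config = config)
    if (!is.null(dir)) out$paths <- .write_synthetic(out, dir)
    return(out)
  }

  # --- exposure and events ------------------------------------------------
  drug_idx <- sample.int(D, n, replace = TRUE, prob = mix$prevalence)
  # per-drug per-pt probability, capped
  pmat <- outer(rep(1, D), pts$p0)
  if (!is.null(config$effects)) {
    di <- match(config$effects$drug, mix$label)
    pj <- match(config$effects$pt, pts$pt)
    pmat[cbind(di, pj)] <- pmat[cbind(di, pj)] * config$effects$rr
  }
  pmat[] <- pmin(1, pmat)

  draw_events <- function(rows) {
    ei <- integer(0); ej <- integer(0)
    for (j in seq_len(K)) {
      hit <- stats::runif(length(rows)) < pmat[drug_idx[rows], j]
      ei <- c(ei, rows[hit])
      ej <- c(ej, rep.int(j, sum(hit)))
    }
    list(i = ei, j = ej)
  }
  ev <- draw_events(seq_len(n))
  n_events <- tabulate(ev$i, nbins = n)
  tries <- 0L
  while (any(n_events == 0L) && tries < 10L) {
    redo <- which(n_events == 0L)
    extra <- draw_events(redo)
    ev$i <- c(ev$i, extra$i); ev$j <- c(ev$j, extra$j)
    n_events <- tabulate(ev$i, nbins = n)
    tries <- tries + 1L
  }
  if (any(n_events == 0L)) {
    left <- which(n_events == 0L)
    forced <- sample.int(K, length(left), replace = TRUE, prob = pts$p0)
    ev$i <- c(ev$i, left); ev$j <- c(ev$j, forced)
  }

  # --- identifiers and dates ----------------------------------------------
  caseid_num <- 10000000 + seq_len(n)
  caseid <- as.character(caseid_num)
  primaryid <- as.character(caseid_num * 10 + 1)

  ws <- as.Date(config$date_range[1], "%Y%m%d")
  we <- as.Date(config$date_range[2], "%Y%m%d")
  span <- as.integer(we - ws) - 120L
  start_date <- ws + sample.int(span, n, replace = TRUE)
  tto_days <- stats::rgeom(n, prob = 1 / (config$tto_mean_days + 1))
  event_date <- start_date + tto_days
  fda_date <- event_date + sample(0:60, n, replace = TRUE)

  start_text <- .fmt_ymd(start_date)
  partial <- stats::runif(n) < config$partial_date_rate
  start_text[partial] <- substr(start_text[partial], 1, 6)
  event_text <- .fmt_ymd(event_date)
  event_text[stats::runif(n) < config$missing_event_dt_rate] <- ""
  fda_text <- .fmt_ymd(fda_date)

  # --- demographics -------------------------------------------------------
  sex <- sample(names(config$sex_split), n, replace = TRUE,
                prob = config$sex_split)
  sex[sex == "unknown"] <- ""
  age_known <- stats::runif(n) >= config$age_unknown_rate
  ar <- config$age_ranges
  band <- sample.int(nrow(ar), n, replace = TRUE, prob = ar$weight)
  age <- ifelse(age_known,
                as.character(floor(ar$min[band] +
                                     stats::runif(n) *
                                     (ar$max[band] - ar$min[band] + 1))),
                "")
  age_cod <- ifelse(age_known, "YR", "")
  country <- sample(c("US", "FR", "GB", "IT", "JP", "DE", "CA", "ES"), n,
                    replace = TRUE,
                    prob = c(0.3, 0.2, 0.15, 0.1, 0.08, 0.07, 0.05, 0.05))
  occp <- sample(c("CN", "MD", "PH", "OT", "HP", ""), n, replace = TRUE,
                 prob = c(0.29, 0.27, 0.19, 0.12, 0.1, 0.03))
  route <- sample(c("Oral", "Intravenous", "Other"), n, replace = TRUE,
                  prob = c(0.5, 0.15, 0.35))
  wt_known <- stats::runif(n) < 0.5
  wt <- ifelse(wt_known,
               sprintf("%.1f", pmax(30, stats::rnorm(n, 70, 15))), "")
  wt_cod <- ifelse(wt_known, "KG", "")
  outc <- sample(c("OT", "HO", "LT", "DE", "DS", ""), n, replace = TRUE,
                 prob = c(0.45, 0.33, 0.07, 0.04, 0.02, 0.09))

  demo <- data.frame(
    PRIMARYID = primaryid, CASEID = caseid, FDA_DT = fda_text,
    EVENT_DT = event_text, SEX = sex, AGE = age, AGE_COD = age_cod,
    OCCP_COD = occp, REPORTER_COUNTRY = country, WT = wt, WT_COD = wt_cod,
    stringsAsFactors = FALSE
  )

  drug <- data.frame(
    PRIMARYID = primaryid, DRUG_SEQ = "1", ROLE_COD = "PS",
    DRUGNAME = mix$label[drug_idx], PROD_AI = mix$label[drug_idx],
    ROUTE = route, START_DT = start_text,
    stringsAsFactors = FALSE
  )
  conc <- which(stats::runif(n) < config$concomitant_rate)
  bg_labels <- mix$label[!(mix$label %in% config$drugs$label)]
  if (length(conc) > 0L && length(bg_labels) > 0L) {
    cdrug <- data.frame(
      PRIMARYID = primaryid[conc], DRUG_SEQ = "2", ROLE_COD = "C",
      DRUGNAME = sample(bg_labels, length(conc), replace = TRUE),
      PROD_AI = "", ROUTE = route[conc], START_DT = "",
      stringsAsFactors = FALSE
    )
    cdrug$PROD_AI <- cdrug$DRUGNAME
    drug <- rbind(drug, cdrug)
  }

  reac <- data.frame(PRIMARYID = primaryid[ev$i], PT = pts$pt[ev$j],
                     stringsAsFactors = FALSE)
  if (config$dup_reaction_rate > 0 && nrow(reac) > 0L) {
    ndup <- floor(config$dup_reaction_rate * nrow(reac))
    if (ndup > 0L) {
      reac <- rbind(reac, reac[sample.int(nrow(reac), ndup), , drop = FALSE])
    }
  }

  outc_tab <- data.frame(PRIMARYID = primaryid[nzchar(outc)],
                         OUTC_COD = outc[nzchar(outc)],
                         stringsAsFactors = FALSE)
  ther <- data.frame(PRIMARYID = primaryid, DSG_DRUG_SEQ = "1",
                     START_DT = start_text, END_DT = "",
                     stringsAsFactors = FALSE)

  # --- duplicates and deletions -------------------------------------------
  n_dup <- floor(config$duplicate_rate * n)
  dup_src <- if (n_dup > 0L) sort(sample.int(n, n_dup)) else integer(0)
  if (n_dup > 0L) {
    clone <- demo[dup_src, , drop = FALSE]
    clone$PRIMARYID <- as.character(caseid_num[dup_src] * 10 + 2)
    clone$FDA_DT <- .fmt_ymd(fda_date[dup_src] + 30)
    demo <- rbind(demo, clone)
    clone_rows <- function(tab, old_pid, new_pid) {
      sel <- tab[tab$PRIMARYID %in% old_pid, , drop = FALSE]
      sel$PRIMARYID <- new_pid[match(sel$PRIMARYID, old_pid)]
      rbind(tab, sel)
    }
    drug <- clone_rows(drug, primaryid[dup_src], clone$PRIMARYID)
    reac <- clone_rows(reac, primaryid[dup_src], clone$PRIMARYID)
    outc_tab <- clone_rows(outc_tab, primaryid[dup_src], clone$PRIMARYID)
    ther <- clone_rows(ther, primaryid[dup_src], clone$PRIMARYID)
  }
  n_del <- floor(config$deleted_rate * n)
  del_case <- if (n_del > 0L) {
    sort(sample(caseid, n_del))
  } else {
    character(0)
  }
  deleted <- data.frame(CASEID = del_case, stringsAsFactors = FALSE)

  rownames(demo) <- rownames(drug) <- rownames(reac) <- NULL
  rownames(outc_tab) <- rownames(ther) <- NULL
  out <- list(tables = list(DEMO = demo, DRUG = drug, REAC = reac,
                            OUTC = outc_tab, THER = ther,
                            DELETED = deleted),
              truth = truth_table(config),
              config = config,
              n_duplicates = n_dup, n_deleted = n_del)
  if (!is.null(dir)) out$paths <- .write_synthetic(out, dir)
  out
}

.write_synthetic <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (kind in names(gen$tables)) {
    p <- file.path(dir, paste0(kind, ".txt"))
    write_faers_table(gen$tables[[kind]], p, kind)
    paths[kind] <- p
  }
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(gen$truth, tp, row.names = FALSE)
  paths["truth"] <- tp
  paths
}

#' Score signal recovery against the generator's ground truth
#'
#' Sensitivity is the fraction of planted pairs (RR > 1 with expected
#' count `E[a] >= min_expected`) flagged as signals; the false-positive
#' rate is the fraction of null pairs (RR = 1) flagged. A pair absent from
#' a signal table (e.g. filtered by the minimum-count rule) counts as not
#' flagged.
#'
#' @param signals a named list (by drug label) of [signal_stats()]
#'   data.frames at PT level, or one such data.frame for a single drug.
#' @param truth a [truth_table()] (or the `truth` element of
#'   [generate_faers()] output).
#' @param min_expected planted pairs below this expected count are excluded
#'   from the sensitivity denominator.
#' @return list with `sensitivity`, `fpr`, `n_positive`, `n_null` and
#'   `decisions` (per-pair data.frame).
#' @export
evaluate_recovery <- function(signals, truth, min_expected = 3) {
  if (is.data.frame(signals)) {
    lbl <- attr(signals, "drug_label")
    if (is.null(lbl)) lbl <- "cohort"
    signals <- stats::setNames(list(signals), lbl)
  }
  truth <- truth[truth$drug %in% names(signals), , drop = FALSE]
  flagged <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    st <- signals[[truth$drug[i]]]
    row <- st[st$event == truth$pt[i], , drop = FALSE]
    flagged[i] <- nrow(row) > 0 && isTRUE(row$signal[1])
  }
  decisions <- cbind(truth, flagged = flagged)
  pos <- truth$rr > 1 & truth$expected_a >= min_expected
  nul <- truth$rr == 1
  list(
    sensitivity = if (any(pos)) mean(flagged[pos]) else NA_real_,
    fpr = if (any(nul)) mean(flagged[nul]) else NA_real_,
    n_positive = sum(pos), n_null = sum(nul),
    decisions = decisions
  )
}
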