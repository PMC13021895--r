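# Shared back half of the pipeline: cleaned records -> cohort -> tables ->
# statistics.
.run_parsed <- function(parsed, lexicon, level, soc_map, min_count,
                        thresholds, priors, strict_single_suspect = FALSE) {
  cleaned <- clean_reports(parsed$demo, parsed$drug, parsed$reac,
                           outc = parsed$outc, ther = parsed$ther,
                           deleted = parsed$deleted)
  cohort <- build_cohort(cleaned$reports, lexicon,
                         strict_single_suspect = strict_single_suspect)
  tab <- build_tables(cleaned$reports, cohort, level = level,
                      soc_map = soc_map, min_count = min_count)
  sig <- signal_stats(tab, thresholds = thresholds, priors = priors)
  list(reports = cleaned$reports, cohort = cohort, tables = tab,
       signals = sig, manifest = cleaned$manifest)
}

#' Run the end-to-end signal analysis on raw FAERS tables
#'
#' Convenience wrapper chaining the pipeline stages: parse the raw tables,
#' clean ([clean_reports()]), build the Primary-Suspect cohort
#' ([build_cohort()]), construct the 2x2 tables ([build_tables()]) and
#' compute the signal statistics ([signal_stats()]).
#'
#' @param tables named list of raw tables (character columns with FAERS
#'   header names) with elements `DEMO`, `DRUG`, `REAC` and optionally
#'   `OUTC`, `THER`, `DELETED` — e.g. the `$tables` element of
#'   [generate_faers()] output.
#' @param lexicon a [drug_lexicon()] defining the cohort.
#' @param level `"PT"` or `"SOC"`.
#' @param soc_map a [soc_mapping()] (required for SOC level).
#' @param min_count minimum event count at PT level.
#' @param thresholds a [default_thresholds()] list.
#' @param priors a [bcpnn_priors()] list.
#' @param strict_single_suspect passed to [build_cohort()].
#' @return list with `reports`, `cohort`, `tables`, `signals`, `manifest`.
#' @export
run_signal_analysis <- function(tables, lexicon, level = "PT",
                                soc_map = NULL, min_count = 3,
                                thresholds = default_thresholds(),
                                priors = bcpnn_priors(),
                                strict_single_suspect = FALSE) {
  parsed <- list(
    demo = parse_faers_records(tables$DEMO, "DEMO"),
    drug = parse_faers_records(tables$DRUG, "DRUG"),
    reac = parse_faers_records(tables$REAC, "REAC"),
    outc = if (!is.null(tables$OUTC))
      parse_faers_records(tables$OUTC, "OUTC"),
    ther = if (!is.null(tables$THER))
      parse_faers_records(tables$THER, "THER"),
    deleted = if (!is.null(tables$DELETED))
      parse_faers_records(tables$DELETED, "DELETED")
  )
  .run_parsed(parsed, lexicon, level, soc_map, min_count, thresholds,
              priors, strict_single_suspect)
}

#' Run the signal analysis from a directory of FAERS-style files
#'
#' @param dir directory holding `DEMO.txt`, `DRUG.txt`, `REAC.txt` and
#'   optionally `OUTC.txt`, `THER.txt`, `DELETED.txt` (as written by
#'   [generate_faers()] or any FAERS-format source).
#' @inheritParams run_signal_analysis
#' @return as [run_signal_analysis()].
#' @export
run_signal_analysis_dir <- function(dir, lexicon, level = "PT",
                                    soc_map = NULL, min_count = 3,
                                    thresholds = default_thresholds(),
                                    priors = bcpnn_priors()) {
  read_if <- function(kind) {
    p <- file.path(dir, paste0(kind, ".txt"))
    if (file.exists(p)) read_faers_table(p, kind) else NULL
  }
  parsed <- list(demo = read_if("DEMO"), drug = read_if("DRUG"),
                 reac = read_if("REAC"), outc = read_if("OUTC"),
                 ther = read_if("THER"), deleted = read_if("DELETED"))
  if (is.null(parsed$demo) || is.null(parsed$drug) || is.null(parsed$reac)) {
    stop("directory must contain DEMO.txt, DRUG.txt and REAC.txt")
  }
  .run_parsed(parsed, lexicon, level, soc_map, min_count, thresholds,
              priors)
}
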