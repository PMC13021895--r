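#!/usr/bin/env Rscript
# Stage 5: time-to-onset analysis.
#
# Computes onset intervals (event date minus drug start date) per cohort
# report with the standard exclusion statuses, then the median/IQR and the
# 0-7 / 7-28 / 28-60 / >=60 day bins, overall and by sex.

source("analysis/00_config.R")

reports <- load_clean_reports()$reports

for (lex in list(mono_lexicon(), combo_lexicon())) {
  cohort <- build_cohort(reports, lex)
  tt <- cohort_tto(reports, lex, cohort)
  write.csv(tt, file.path(OUT_DIR, sprintf("tto_%s.csv", lex$target_label)),
            row.names = FALSE)
  rows <- list()
  for (sx in c("all", "F", "M")) {
    ids <- if (sx == "all") cohort$report_ids else
      intersect(cohort$report_ids,
                reports$demo$primaryid[reports$demo$sex == sx])
    s <- summarize_tto(tt[tt$primaryid %in% ids, ])
    rows[[sx]] <- data.frame(sex = sx, n_valid = s$n_valid,
                             n_unknown = s$n_unknown, median = s$median,
                             q1 = s$q1, q3 = s$q3,
                             t(stats::setNames(s$bins$n,
                                               paste0("bin_", s$bins$bin))))
    message(sprintf("%s [%s]: median %.0f days (IQR %.0f-%.0f), n=%d",
                    lex$target_label, sx, s$median, s$q1, s$q3, s$n_valid))
  }
  write.csv(do.call(rbind, rows),
            file.path(OUT_DIR, sprintf("tto_summary_%s.csv",
                                       lex$target_label)),
            row.names = FALSE)
}
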