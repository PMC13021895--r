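#!/usr/bin/env Rscript
# Stage 3: disproportionality signal tables.
#
# For each cohort, builds the PT- and SOC-level 2x2 tables against the
# all-other-reports background and computes ROR, PRR, chi-squared, BCPNN
# IC/IC025 and EBGM/EBGM05 with the joint four-algorithm decision.

source("analysis/00_config.R")

reports <- load_clean_reports()$reports
socmap <- study_soc_mapping()

for (lex in list(mono_lexicon(), combo_lexicon())) {
  cohort <- build_cohort(reports, lex)
  for (level in c("PT", "SOC")) {
    tab <- build_tables(reports, cohort, level = level,
                        soc_map = if (level == "SOC") socmap)
    sig <- signal_stats(tab)
    out <- file.path(OUT_DIR, sprintf("signals_%s_%s.csv",
                                      lex$target_label, level))
    write_signal_table(sig, out)
    hits <- sig[sig$signal, ]
    message(sprintf("%s %s level: %d events, %d signals",
                    lex$target_label, level, nrow(sig), nrow(hits)))
    if (nrow(hits) > 0) {
      top <- hits[order(-hits$ror), ][seq_len(min(3, nrow(hits))), ]
      for (k in seq_len(nrow(top))) {
        message(sprintf("  %s: a=%d ROR %.2f (%.2f, %.2f) IC025 %.2f",
                        top$event[k], top$a[k], top$ror[k], top$ror_lo[k],
                        top$ror_hi[k], top$ic025[k]))
      }
    }
  }
}
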