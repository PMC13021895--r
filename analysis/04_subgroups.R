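#!/usr/bin/env Rscript
# Stage 4: sex and age subgroup signal analyses.
#
# Re-runs the PT-level disproportionality analysis inside each sex and age
# stratum (cohort and background both restricted to the stratum) and writes
# one signal table per (drug, stratum).

source("analysis/00_config.R")

reports <- load_clean_reports()$reports

strata <- list(F = stratum_spec(sex = "F"),
               M = stratum_spec(sex = "M"),
               under60 = stratum_spec(age_group = "under60"),
               over60 = stratum_spec(age_group = "over_or_equal_60"))

for (lex in list(mono_lexicon(), combo_lexicon())) {
  cohort <- build_cohort(reports, lex)
  for (nm in names(strata)) {
    sub <- run_subgroup(reports, cohort, strata[[nm]])
    out <- file.path(OUT_DIR, sprintf("signals_%s_%s_PT.csv",
                                      lex$target_label, nm))
    write_signal_table(sub$signals, out)
    message(sprintf("%s / %s: cohort %d, %d signals",
                    lex$target_label, nm,
                    attr(sub$tables, "n_cohort"),
                    sum(sub$signals$signal)))
  }
}
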