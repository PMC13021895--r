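#!/usr/bin/env Rscript
# Stage 2: clean the report tables.
#
# Deduplicates by case (latest FDA_DT, then largest PRIMARYID), removes
# deleted cases, drops chronologically inconsistent reports, and writes
# the step-by-step manifest plus per-cohort demographic summaries.

source("analysis/00_config.R")

cleaned <- load_clean_reports()
write.csv(cleaned$manifest, file.path(OUT_DIR, "cleaning_manifest.csv"),
          row.names = FALSE)
message("cleaning manifest:")
print(cleaned$manifest)

reports <- cleaned$reports
for (lex in list(mono_lexicon(), combo_lexicon())) {
  cohort <- build_cohort(reports, lex)
  ds <- summarize_demographics(reports, cohort)
  out <- file.path(OUT_DIR, sprintf("demographics_%s.csv", lex$target_label))
  blocks <- c("sex", "age_group", "reporter", "outcome", "country",
              "route", "year")
  tab <- do.call(rbind, lapply(blocks, function(b)
    cbind(block = b, ds[[b]])))
  write.csv(tab, out, row.names = FALSE)
  message(sprintf(
    "%s: %d reports; median age %.0f (IQR %.0f-%.0f); %.1f%% female",
    lex$target_label, ds$n_reports, ds$age_summary$median,
    ds$age_summary$q1, ds$age_summary$q3,
    ds$sex$pct[ds$sex$category == "F"]))
}
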