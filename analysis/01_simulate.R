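#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study database.
#
# Writes FAERS-format tables (DEMO/DRUG/REAC/OUTC/THER/DELETED) plus the
# ground-truth rate-ratio table under results/synthetic/.

source("analysis/00_config.R")

cfg <- study_config()
gen <- generate_faers(cfg, dir = SYN_DIR)

message(sprintf("generated %d base reports (+%d duplicates, %d deleted)",
                cfg$n_reports, gen$n_duplicates, gen$n_deleted))
message(sprintf("planted effects: %d drug-event pairs with RR > 1",
                sum(gen$truth$rr > 1)))
message("tables written to ", SYN_DIR)
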