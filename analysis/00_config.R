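# Shared study configuration for the analysis scripts: a synthetic
# spontaneous-reporting database contrasting a monotherapy-like drug
# (immune/skin-dominated risk profile) with a combination-like drug
# (hepatobiliary-dominated profile), mirroring the kind of beta-lactam
# comparison the pipeline is built for.

library(faersdispro)

STUDY_SEED <- 20260927
SYN_DIR <- "results/synthetic"
OUT_DIR <- "results"
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

study_config <- function(seed = STUDY_SEED) {
  synthetic_config(
    seed = seed,
    n_reports = 60000,
    drugs = data.frame(label = c("DRUG_MONO", "DRUG_COMBO"),
                       prevalence = c(0.12, 0.09)),
    pts = default_pt_panel(),
    effects = data.frame(
      drug = c("DRUG_MONO", "DRUG_MONO", "DRUG_MONO", "DRUG_MONO",
               "DRUG_COMBO", "DRUG_COMBO", "DRUG_COMBO"),
      pt = c("Urticaria", "Angioedema", "Anaphylactic shock",
             "Type I hypersensitivity",
             "Drug-induced liver injury", "Cholestatic hepatitis", "Rash"),
      rr = c(2.5, 4, 6, 8, 12, 10, 2))
  )
}

mono_lexicon <- function() drug_lexicon("DRUG_MONO", "DRUG_MONO")
combo_lexicon <- function() drug_lexicon("DRUG_COMBO", "DRUG_COMBO")

study_soc_mapping <- function() {
  p <- default_pt_panel()
  soc_mapping(p$pt, p$soc)
}

load_clean_reports <- function() {
  parsed <- lapply(
    stats::setNames(nm = c("DEMO", "DRUG", "REAC", "OUTC", "THER",
                           "DELETED")),
    function(k) read_faers_table(file.path(SYN_DIR, paste0(k, ".txt")), k))
  clean_reports(parsed$DEMO, parsed$DRUG, parsed$REAC, outc = parsed$OUTC,
                ther = parsed$THER, deleted = parsed$DELETED)
}
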