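#!/usr/bin/env Rscript
# Stage 1 — simulate the cohort.
#
# Generates a synthetic FTD cohort at the study's scale: 70 bvFTD, 36
# svPPA, 30 nfvPPA patients and 50 matched controls, a 12-test cognitive
# battery and 102 atlas-regional DBM values sharing four planted latent
# variables, plus ~1-year follow-up visits for 32 patients. A few
# education values are blanked to exercise the imputation step downstream.

library(ftdpls)
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

cfg <- sim_config(seed = seed)
sim <- generate_cohort(cfg)
patients <- sim$cohort$data$subject_id[sim$cohort$data$group != "control"]
set.seed(seed + 10L)
fu_subjects <- sample(patients, 32)
cohort <- generate_followup(sim$cohort, sim$truth, cfg,
                            subjects = fu_subjects, seed = seed + 11L)

set.seed(seed + 12L)
miss <- sample(which(cohort$data$visit == "baseline"), 6)
cohort$data$education[miss] <- NA

write_cohort(cohort, file.path(out, "cohort.tsv"))
jsonlite::write_json(list(cog_cols = cohort$cog_cols,
                          brain_cols = cohort$brain_cols, seed = seed),
                     file.path(out, "schema.json"))
utils::write.table(
  data.frame(variable = rownames(sim$truth$U_true), sim$truth$U_true),
  file.path(out, "truth_saliences_x.tsv"), sep = "\t", row.names = FALSE,
  quote = FALSE)
utils::write.table(
  data.frame(region = rownames(sim$truth$V_true), sim$truth$V_true),
  file.path(out, "truth_saliences_y.tsv"), sep = "\t", row.names = FALSE,
  quote = FALSE)
jsonlite::write_json(list(rho_target = sim$truth$rho_target,
                          rho_realized = sim$truth$rho_realized),
                     file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA)

print(cohort)
cat(sprintf("Planted %d LVs; realized within-group latent correlations: %s\n",
            cfg$n_latent,
            paste(sprintf("%.2f", sim$truth$rho_realized), collapse = ", ")))
cat(sprintf("Blanked %d education values for the imputation demo.\n",
            length(miss)))
cat("Mean follow-up interval:",
    sprintf("%.2f years\n",
            mean(cohort$data$years_since_baseline[
              cohort$data$visit == "followup"])))
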