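#!/usr/bin/env Rscript
# Stage 3 — behavioural PLS.
#
# Z-scores the baseline patient blocks, decomposes the 12 x 102
# cognition-brain correlation matrix, tests each latent variable with 500
# row permutations, and derives bootstrap ratios (500 resamples) for every
# salience weight with 95%-CI thresholding. Writes the LV summary,
# saliences, bootstrap ratios and subject projection scores.

library(ftdpls)
out <- "results/analysis"
schema <- jsonlite::fromJSON(file.path(out, "schema.json"))
cohort <- read_cohort(file.path(out, "cohort_preprocessed.tsv"), schema)
seed <- schema$seed

base <- cohort$data[cohort$data$visit == "baseline" &
                      cohort$data$group != "control", ]
X <- as.matrix(base[cohort$cog_cols]); rownames(X) <- base$subject_id
Y <- as.matrix(base[cohort$brain_cols]); rownames(Y) <- base$subject_id

fit <- pls_fit(X, Y, n_perm = 500, n_boot = 500, seed = seed + 20L)
print(fit)

lv_summary <- data.frame(LV = seq_along(fit$perm_p),
                         covexp_pct = 100 * fit$covexp,
                         perm_p = fit$perm_p)
utils::write.table(lv_summary, file.path(out, "lv_summary.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
for (side in c("x", "y")) {
  sal <- if (side == "x") fit$U else fit$V
  bsr <- fit[[paste0("bsr_", side)]]
  utils::write.table(data.frame(variable = rownames(sal), sal),
                     file.path(out, paste0("saliences_", side, ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(variable = rownames(bsr), bsr),
                     file.path(out, paste0("bootstrap_ratios_", side, ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}
scores <- data.frame(subject_id = base$subject_id, group = base$group,
                     fit$score_x, fit$score_y)
colnames(scores)[-(1:2)] <- c(paste0("cogscore_lv", seq_len(fit$K)),
                              paste0("brainscore_lv", seq_len(fit$K)))
utils::write.table(scores, file.path(out, "scores.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

cat(sprintf("\n%d LV(s) significant at permuted p < 0.05; top-4 explain %.1f%% of cross-block covariance.\n",
            sum(fit$perm_p < 0.05), 100 * sum(fit$covexp[1:4])))
top <- order(-abs(fit$bsr_x[, 1]))[1:5]
cat("LV-1 strongest cognition contributors (by |BSR|):\n")
print(data.frame(variable = rownames(fit$bsr_x)[top],
                 salience = round(fit$U[top, 1], 3),
                 bsr = round(fit$bsr_x[top, 1], 2),
                 significant = fit$sig_mask_x[top, 1]), row.names = FALSE)
cat(sprintf("LV-1 brain regions passing the 95%% BSR criterion: %d of %d\n",
            sum(fit$sig_mask_y[, 1]), nrow(fit$V)))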