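#!/usr/bin/env Rscript
# Stage 5 — subtype classification.
#
# Bagged linear-discriminant ensembles (100 learners) on PLS-score feature
# sets under stratified 10-fold CV repeated over 20 randomized splits:
# maximal (both blocks' scores + age/sex/education), brain-only,
# cognition-only, and a minimal model whose PLS is refit on the short
# battery (CDR subscales + BNT). Validation repeats the maximal model in a
# severity-filtered (CDR sum of boxes) and an age-matched subsample.

library(ftdpls)
out <- "results/analysis"
schema <- jsonlite::fromJSON(file.path(out, "schema.json"))
cohort <- read_cohort(file.path(out, "cohort_preprocessed.tsv"), schema)
seed <- schema$seed
scores <- utils::read.delim(file.path(out, "scores.tsv"))
base <- cohort$data[cohort$data$visit == "baseline" &
                      cohort$data$group != "control", ]
stopifnot(identical(scores$subject_id, base$subject_id))
K <- sum(grepl("^cogscore_lv", names(scores)))
sx <- as.matrix(scores[paste0("cogscore_lv", seq_len(K))])
sy <- as.matrix(scores[paste0("brainscore_lv", seq_len(K))])
fit_like <- list(score_x = sx, score_y = sy)
labels <- factor(base$group)

run <- function(feats, name) {
  rep <- cv_repeated(feats, labels, k = 10, n_repeats = 20, B = 100,
                     seed = seed + 40L)
  cat(sprintf("%-16s accuracy %.2f%% (SD %.2f%%)\n", name,
              rep$accuracy_mean, rep$accuracy_sd))
  rep
}

metrics <- list()
metrics$maximal <- run(build_features(fit_like, base, "maximal"), "maximal")
metrics$brain_only <- run(build_features(fit_like, base, "brain_only"),
                          "brain only")
metrics$cognition_only <- run(build_features(fit_like, base,
                                             "cognition_only"),
                              "cognition only")

X <- as.matrix(base[cohort$cog_cols]); rownames(X) <- base$subject_id
Y <- as.matrix(base[cohort$brain_cols]); rownames(Y) <- base$subject_id
fit_min <- pls_fit(X[, c("cdr_sumboxes", "cdr_language", "cdr_behaviour",
                         "bnt")], Y,
                   n_perm = 500, n_boot = 2, seed = seed + 30L)
metrics$minimal <- run(build_features(fit_min, base, "maximal"), "minimal")

cat("\nPer-class metrics, maximal model (mean over repeats):\n")
print(round(metrics$maximal$per_class_mean, 2))

# validation subsamples
sev <- matched_subsample(cohort, list(type = "threshold",
                                      column = "cdr_sumboxes", max = 1.5))
keep <- scores$subject_id %in% sev$cohort$data$subject_id
if (length(unique(labels[keep])) == 3 && all(table(labels[keep]) >= 10)) {
  rep_sev <- cv_repeated(build_features(fit_like, base, "maximal")[keep, ],
                         labels[keep], k = 10, n_repeats = 20, B = 100,
                         seed = seed + 41L)
  cat(sprintf("\nseverity-matched (CDR < 1.5, n = %d): accuracy %.2f%%\n",
              sum(keep), rep_sev$accuracy_mean))
  metrics$severity_matched <- rep_sev
}
agm <- matched_subsample(cohort, list(type = "age_match", caliper = 5))
keep <- scores$subject_id %in% agm$cohort$data$subject_id
rep_age <- cv_repeated(build_features(fit_like, base, "maximal")[keep, ],
                       labels[keep], k = 10, n_repeats = 20, B = 100,
                       seed = seed + 42L)
cat(sprintf("age-matched (n = %d): accuracy %.2f%%\n", sum(keep),
            rep_age$accuracy_mean))
metrics$age_matched <- rep_age

summ <- lapply(metrics, function(m)
  list(accuracy_mean = m$accuracy_mean, accuracy_sd = m$accuracy_sd,
       per_class = as.data.frame(m$per_class_mean), protocol = m$protocol))
jsonlite::write_json(summ, file.path(out, "metrics.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE)
for (n in names(metrics))
  utils::write.table(metrics[[n]]$confusion,
                     file.path(out, paste0("confusion_", n, ".tsv")),
                     sep = "\t", quote = FALSE)
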