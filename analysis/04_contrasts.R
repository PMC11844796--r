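#!/usr/bin/env Rscript
# Stage 4 — group differences between variants.
#
# For each retained LV, regresses the cognition-side score on the
# brain-side score with variant main effects and interactions, and
# extracts all pairwise intercept and slope contrasts with BH-FDR
# correction within each LV's family of six.

library(ftdpls)
out <- "results/analysis"
scores <- utils::read.delim(file.path(out, "scores.tsv"))
K <- sum(grepl("^cogscore_lv", names(scores)))

rows <- lapply(seq_len(K), function(k) {
  res <- interaction_regression(scores[[paste0("cogscore_lv", k)]],
                                scores[[paste0("brainscore_lv", k)]],
                                scores$group, lv = k)
  cat(sprintf("LV-%d: adjusted R^2 = %.3f\n", k, res$adj_r_squared))
  res$contrasts
})
contrasts <- do.call(rbind, rows)
utils::write.table(contrasts, file.path(out, "contrasts.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

sig <- contrasts[contrasts$p_fdr < 0.05, ]
cat(sprintf("\n%d of %d contrasts significant after FDR:\n",
            nrow(sig), nrow(contrasts)))
if (nrow(sig)) print(sig[, c("lv", "contrast", "term", "tStat", "p_fdr")],
                     row.names = FALSE, digits = 3)
cat("\n(slope contrasts say whether the atrophy pattern impacts the\n",
    "cognitive profile differently across FTD variants)\n")
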