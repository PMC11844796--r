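# Subtype-difference regressions: cognition score ~ brain score * variant,
# pairwise intercept/slope contrasts with BH false-discovery-rate control.

#' Interaction regression between brain and cognition scores across variants
#'
#' Fits the OLS model
#' \code{cognition_score ~ brain_score + variant + brain_score:variant}
#' with dummy-coded variant, then extracts all three pairwise intercept and
#' slope contrasts by reference-level rotation. The slope contrasts say
#' whether the impact of the atrophy pattern on the cognitive profile
#' differs between FTD subtypes. Estimates are invariant to the choice of
#' reference group; p-values are BH-adjusted within the LV's family of six
#' contrasts (3 pairs x intercept/slope).
#'
#' @param cog_score Numeric vector: cognition-block projection score
#'   (response).
#' @param brain_score Numeric vector: brain-block projection score
#'   (predictor).
#' @param groups Factor/character with exactly 3 levels, >= 3 subjects per
#'   level.
#' @param lv LV index carried into the output (default 1).
#' @return List with \code{contrasts} (data.frame: lv, contrast, term,
#'   estimate, tStat, p_raw, p_fdr, n), \code{adj_r_squared} and the base
#'   \code{model}.
#' @export
interaction_regression <- function(cog_score, brain_score, groups, lv = 1L) {
  groups <- factor(groups)
  lev <- levels(droplevels(groups))
  if (length(lev) != 3)
    stop("exactly 3 group levels required, got ", length(lev))
  if (any(table(groups) < 3))
    stop("every group needs at least 3 subjects")
  if (stats::sd(brain_score) == 0) stop("constant brain score")
  d <- data.frame(cog = cog_score, brain = brain_score, grp = groups)

  rows <- list()
  base_fit <- NULL
  for (ref in lev) {
    d$grp <- stats::relevel(factor(d$grp), ref = ref)
    fit <- stats::lm(cog ~ brain * grp, data = d)
    if (is.null(base_fit)) base_fit <- fit
    ct <- summary(fit)$coefficients
    others <- setdiff(lev, ref)
    for (g in others) {
      pair <- paste(sort(c(ref, g)), collapse = " vs ")
      key_i <- paste0("grp", g)
      key_s <- paste0("brain:grp", g)
      rows[[paste(pair, "intercept", ref)]] <- data.frame(
        lv = lv, contrast = pair, term = "intercept", ref = ref,
        estimate = ct[key_i, 1], tStat = ct[key_i, 3], p_raw = ct[key_i, 4])
      rows[[paste(pair, "slope", ref)]] <- data.frame(
        lv = lv, contrast = pair, term = "slope", ref = ref,
        estimate = ct[key_s, 1], tStat = ct[key_s, 3], p_raw = ct[key_s, 4])
    }
  }
  all_rows <- do.call(rbind, rows)
  # each pair appears under two reference codings with opposite signs;
  # keep the coding whose reference is the alphabetically first group
  all_rows$first <- vapply(strsplit(all_rows$contrast, " vs "), `[`, "", 1)
  res <- all_rows[all_rows$ref == all_rows$first,
                  c("lv", "contrast", "term", "estimate", "tStat", "p_raw")]
  res <- res[order(res$contrast, res$term), ]
  res$p_fdr <- fdr_bh(res$p_raw)
  res$adj_r_squared <- summary(base_fit)$adj.r.squared
  res$n <- nrow(d)
  rownames(res) <- NULL
  list(contrasts = res, adj_r_squared = summary(base_fit)$adj.r.squared,
       model = base_fit, rotations = all_rows)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone non-decreasing in rank and capped
#' at 1.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
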