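# End-to-end orchestration: simulate -> preprocess -> PLS -> contrasts ->
# classify -> longitudinal, from one config with one master seed. Every
# stage writes plain-text artifacts; a JSON manifest records seeds, stage
# timings and output checksums so identical configs reproduce identical
# numeric outputs.

write_tsv <- function(x, path, rownames_as = NULL) {
  d <- as.data.frame(x)
  if (!is.null(rownames_as)) {
    if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
    d <- cbind(stats::setNames(data.frame(rownames(x),
                                          stringsAsFactors = FALSE),
                               rownames_as), d)
  }
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Assemble classifier feature sets from a PLS fit
#'
#' \code{maximal}: cognition- and brain-block LV scores plus
#' age/sex/education; \code{brain_only} / \code{cognition_only}: one
#' block's scores plus covariates; \code{scores_only}: both blocks, no
#' covariates. Sex enters as 0/1 (F/M).
#'
#' @param fit A \code{\link{pls_fit}} (or any object with score_x/score_y).
#' @param demo data.frame with age, sex, education aligned to score rows.
#' @param set Feature set name.
#' @param covariates Append demographic covariates (default TRUE except
#'   for \code{scores_only}).
#' @return Numeric feature matrix.
#' @export
build_features <- function(fit, demo,
                           set = c("maximal", "brain_only",
                                   "cognition_only", "scores_only"),
                           covariates = !identical(set, "scores_only")) {
  set <- match.arg(set)
  sx <- fit$score_x; sy <- fit$score_y
  colnames(sx) <- paste0("cogscore_lv", seq_len(ncol(sx)))
  colnames(sy) <- paste0("brainscore_lv", seq_len(ncol(sy)))
  feats <- switch(set,
    maximal = cbind(sx, sy),
    scores_only = cbind(sx, sy),
    brain_only = sy,
    cognition_only = sx)
  if (covariates) {
    feats <- cbind(feats, age = demo$age,
                   sex = as.numeric(demo$sex == "M"),
                   education = demo$education)
  }
  feats
}

#' Run the full analysis pipeline
#'
#' Executes all stages on a synthetic cohort and writes every artifact
#' under \code{out_dir}: the cohort and planted truth, PLS LV summary,
#' saliences, bootstrap ratios and subject scores, per-LV pairwise
#' regression contrasts, classifier metrics per feature set, longitudinal
#' rates and tests, and a manifest. All randomness derives from the
#' config's seed by fixed offsets.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Output directory (created if needed).
#' @param n_perm,n_boot PLS permutation / bootstrap counts (500 each by
#'   default, the standard protocol).
#' @param alpha Significance level for LV retention and BSR thresholds.
#' @param n_followup Number of patients given a follow-up visit
#'   (default 32).
#' @param feature_sets Classifier feature sets to evaluate.
#' @param k,n_repeats,B Cross-validation folds, randomized repeats, and
#'   learners per ensemble.
#' @param use_wscore Adjust patient variables to control-referenced
#'   w-scores before the PLS (sensitivity analysis; default FALSE).
#' @param minimal_cog Cognition columns of the "minimal" feature set; the
#'   PLS is refit on this reduced battery (default: CDR subscales + BNT).
#' @return The run manifest (list), invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         n_perm = 500, n_boot = 500, alpha = 0.05,
                         n_followup = 32,
                         feature_sets = c("maximal", "brain_only",
                                          "cognition_only", "minimal"),
                         k = 10, n_repeats = 100, B = 100,
                         use_wscore = FALSE,
                         minimal_cog = c("cdr_sumboxes", "cdr_language",
                                         "cdr_behaviour", "bnt")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, stages = list(), artifacts = list())
  tick <- function(stage, start) {
    manifest$stages[[stage]] <<- round(
      as.numeric(difftime(Sys.time(), start, units = "secs")), 2)
  }

  ## stage 1: simulate -------------------------------------------------
  s <- Sys.time()
  sim <- generate_cohort(config)
  patients <- sim$cohort$data$subject_id[sim$cohort$data$group != "control"]
  fu_subjects <- with_seed(config$seed + 10L,
                           sample(patients, min(n_followup, length(patients))))
  cohort <- generate_followup(sim$cohort, sim$truth, config,
                              subjects = fu_subjects,
                              seed = config$seed + 11L)
  write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
  write_tsv(sim$truth$U_true, file.path(out_dir, "truth_saliences_x.tsv"),
            rownames_as = "variable")
  write_tsv(sim$truth$V_true, file.path(out_dir, "truth_saliences_y.tsv"),
            rownames_as = "region")
  jsonlite::write_json(
    list(rho_target = sim$truth$rho_target,
         rho_realized = sim$truth$rho_realized,
         group_assignments = as.list(sim$truth$group_assignments)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  tick("simulate", s)

  ## stage 2: preprocess ------------------------------------------------
  s <- Sys.time()
  cohort <- impute_group_mean(cohort, "education")
  cc <- complete_case_filter(cohort, c(cohort$cog_cols, "age", "sex",
                                       "education"))
  cohort <- cc$cohort
  base <- cohort$data[cohort$data$visit == "baseline", ]
  pat <- base[base$group != "control", ]
  ctl <- base[base$group == "control", ]
  X <- as.matrix(pat[cohort$cog_cols]); rownames(X) <- pat$subject_id
  Y <- as.matrix(pat[cohort$brain_cols]); rownames(Y) <- pat$subject_id
  if (use_wscore) {
    X <- wscore_adjust(pat, ctl, cohort$cog_cols)
    Y <- wscore_adjust(pat, ctl, cohort$brain_cols)
  }
  tick("preprocess", s)

  ## stage 3: PLS -------------------------------------------------------
  s <- Sys.time()
  fit <- pls_fit(X, Y, n_perm = n_perm, n_boot = n_boot, alpha = alpha,
                 seed = config$seed + 20L)
  lv_summary <- data.frame(
    LV = seq_along(fit$perm_p),
    d = svd_latent_variables(cross_block_correlation(
      zscore_columns(X)$block, zscore_columns(Y)$block))$d,
    covexp = fit$covexp, perm_p = fit$perm_p)
  write_tsv(lv_summary, file.path(out_dir, "lv_summary.tsv"))
  write_tsv(fit$U, file.path(out_dir, "saliences_x.tsv"),
            rownames_as = "variable")
  write_tsv(fit$V, file.path(out_dir, "saliences_y.tsv"),
            rownames_as = "region")
  write_tsv(fit$bsr_x, file.path(out_dir, "bootstrap_ratios_x.tsv"),
            rownames_as = "variable")
  write_tsv(fit$bsr_y, file.path(out_dir, "bootstrap_ratios_y.tsv"),
            rownames_as = "region")
  scores_df <- data.frame(subject_id = pat$subject_id, group = pat$group,
                          fit$score_x, fit$score_y)
  colnames(scores_df)[-(1:2)] <- c(
    paste0("cogscore_lv", seq_len(fit$K)),
    paste0("brainscore_lv", seq_len(fit$K)))
  write_tsv(scores_df, file.path(out_dir, "scores.tsv"))
  tick("pls", s)

  ## stage 4: contrasts ---------------------------------------------------
  s <- Sys.time()
  contrast_rows <- lapply(seq_len(fit$K), function(kk)
    interaction_regression(fit$score_x[, kk], fit$score_y[, kk],
                           pat$group, lv = kk)$contrasts)
  contrasts <- do.call(rbind, contrast_rows)
  write_tsv(contrasts, file.path(out_dir, "contrasts.tsv"))
  tick("contrasts", s)

  ## stage 5: classify ----------------------------------------------------
  s <- Sys.time()
  labels <- factor(pat$group)
  metrics <- list()
  for (fs in feature_sets) {
    if (fs == "minimal") {
      mc <- intersect(minimal_cog, cohort$cog_cols)
      if (length(mc) < 2) stop("minimal cognition battery not in cohort")
      fit_min <- pls_fit(X[, mc, drop = FALSE], Y, n_perm = n_perm,
                         n_boot = 2, alpha = alpha,
                         seed = config$seed + 30L)
      feats <- build_features(fit_min, pat, "maximal")
    } else {
      feats <- build_features(fit, pat, fs)
    }
    rep <- cv_repeated(feats, labels, k = k, n_repeats = n_repeats, B = B,
                       seed = config$seed + 40L)
    metrics[[fs]] <- list(
      accuracy_mean = rep$accuracy_mean, accuracy_sd = rep$accuracy_sd,
      per_class = as.data.frame(rep$per_class_mean),
      protocol = rep$protocol)
    write_tsv(rep$confusion, file.path(out_dir,
                                       paste0("confusion_", fs, ".tsv")),
              rownames_as = "true_class")
  }
  tick("classify", s)

  ## stage 6: longitudinal ------------------------------------------------
  s <- Sys.time()
  fu <- cohort$data[cohort$data$visit == "followup", ]
  longi <- NULL
  if (nrow(fu) >= 6) {
    Xf <- as.matrix(fu[cohort$cog_cols]); rownames(Xf) <- fu$subject_id
    Yf <- as.matrix(fu[cohort$brain_cols]); rownames(Yf) <- fu$subject_id
    Xfz <- zscore_columns(Xf, fit$stats_x)$block
    Yfz <- zscore_columns(Yf, fit$stats_y)$block
    sc_fu <- project_scores(Xfz, Yfz, fit)
    rownames(sc_fu$score_x) <- fu$subject_id
    rownames(sc_fu$score_y) <- fu$subject_id
    sc_base <- list(score_x = fit$score_x, score_y = fit$score_y)
    rates <- rate_records(sc_base, sc_fu,
                          stats::setNames(fu$years_since_baseline,
                                          fu$subject_id))
    rates$group <- pat$group[match(rates$subject_id, pat$subject_id)]
    write_tsv(rates, file.path(out_dir, "rates.tsv"))
    tests <- list()
    for (blk in c("score_x", "score_y")) for (kk in seq_len(fit$K)) {
      rr <- rates[rates$block == blk & rates$lv == kk, ]
      pc <- paired_change_test(rr$baseline, rr$followup)
      tests[[paste(blk, kk, "paired")]] <- data.frame(
        lv = kk, block = blk, test = "paired_change",
        contrast = "followup vs baseline",
        stat = pc$t, p = pc$p, p_fdr = NA, n = pc$n)
      if (all(table(rr$group) >= 2)) {
        gc <- group_rate_contrasts(rr$rate, rr$group)
        tests[[paste(blk, kk, "rates")]] <- data.frame(
          lv = kk, block = blk, test = "rate_contrast",
          contrast = gc$contrast, stat = gc$tStat, p = gc$p_tukey,
          p_fdr = NA, n = sum(gc$n1[1], gc$n2[1], na.rm = TRUE))
      }
    }
    tests_df <- do.call(rbind, tests)
    paired <- tests_df$test == "paired_change"
    tests_df$p_fdr[paired] <- fdr_bh(tests_df$p[paired])
    write_tsv(tests_df, file.path(out_dir, "longitudinal_tests.tsv"))
    fu_feats <- build_features(list(score_x = sc_fu$score_x,
                                    score_y = sc_fu$score_y), fu, "maximal")
    base_feats <- build_features(fit, pat, "maximal")
    longi <- longitudinal_validate(
      base_feats, labels, pat$subject_id,
      fu_feats, factor(fu$group, levels(labels)), fu$subject_id,
      k = k, n_repeats = n_repeats, B = B, seed = config$seed + 50L)
    metrics$longitudinal <- list(accuracy_mean = longi$accuracy_mean,
                                 accuracy_sd = longi$accuracy_sd,
                                 audit = longi$audit)
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  tick("longitudinal", s)

  files <- list.files(out_dir, full.names = TRUE)
  manifest$artifacts <- as.list(tools::md5sum(files))
  names(manifest$artifacts) <- basename(files)
  manifest$elapsed_sec <- round(
    as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
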