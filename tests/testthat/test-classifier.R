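# Bagged discriminant ensemble, CV protocols, metrics, matched subsamples.

test_that("a degenerate ensemble equals a single discriminant classifier", {
  sep <- separable_classes(n_per_class = 30, gap = 3)
  model <- fit_ensemble(sep$x, sep$y, B = 1, seed = 1, resample = FALSE)
  ours <- predict_majority(model, sep$x)
  ref <- as.character(predict(MASS::lda(sep$x, grouping = sep$y),
                              sep$x)$class)
  expect_equal(mean(ours == ref), 1)
})

test_that("well-separated classes are classified near-perfectly", {
  sep <- separable_classes(n_per_class = 70, gap = 6)   # ~6 pooled SDs
  model <- fit_ensemble(sep$x, sep$y, B = 25, seed = 2)
  expect_gte(mean(predict_majority(model, sep$x) == sep$y) * 100, 99)
})

test_that("ensembles are deterministic given a seed and validate inputs", {
  sep <- separable_classes(n_per_class = 15, gap = 2)
  m1 <- fit_ensemble(sep$x, sep$y, B = 10, seed = 5)
  m2 <- fit_ensemble(sep$x, sep$y, B = 10, seed = 5)
  expect_identical(predict_majority(m1, sep$x), predict_majority(m2, sep$x))
  expect_error(fit_ensemble(sep$x, rep("a", nrow(sep$x))), "2 classes")
  expect_error(fit_ensemble(sep$x, c("b", rep("a", nrow(sep$x) - 1))),
               "at least 2 training members")
  expect_error(predict_majority(m1, sep$x[, 1, drop = FALSE]),
               "column count")
})

test_that("majority vote equals an explicit vote-counting oracle", {
  set.seed(6)
  sep <- separable_classes(n_per_class = 20, gap = 1.5)
  model <- fit_ensemble(sep$x, sep$y, B = 15, seed = 3)
  newx <- sep$x + rnorm(length(sep$x), sd = 0.5)
  pred <- predict_majority(model, newx)
  # oracle: per-learner argmax, explicit tally, ties -> mean posterior,
  # then lexicographic
  votes <- sapply(model$learners, function(lr) {
    sc <- as.matrix(newx) %*% lr$A
    sc <- sweep(sc, 2, lr$const, "+")
    lr$classes[max.col(sc, ties.method = "first")]
  })
  for (i in seq_len(nrow(newx))) {
    tab <- table(factor(votes[i, ], model$classes))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) expect_identical(pred[i], top)
    else expect_true(pred[i] %in% top)
  }
})

test_that("engineered vote ties break deterministically", {
  # two learners trained on mirrored data vote for different classes;
  # the tie resolves by mean posterior, reproducibly
  x <- matrix(c(-2, -1.8, 2, 2.2, -2.1, 2.1), ncol = 1)
  y <- factor(c("a", "a", "b", "b", "a", "b"))
  m <- fit_ensemble(x, y, B = 2, seed = 9, resample = FALSE)
  p1 <- predict_majority(m, matrix(c(0, 0.05), ncol = 1))
  p2 <- predict_majority(m, matrix(c(0, 0.05), ncol = 1))
  expect_identical(p1, p2)
  expect_true(all(p1 %in% c("a", "b")))
})

test_that("classification metrics match hand computation", {
  cm <- matrix(c(5, 1, 0,
                 2, 6, 1,
                 0, 0, 7), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  met <- classification_metrics(cm)
  # class a: TP 5, FN 1, FP 2, TN 14
  expect_equal(met$per_class$sensitivity[1], 100 * 5 / 6)
  expect_equal(met$per_class$specificity[1], 100 * 14 / 16)
  expect_equal(met$per_class$balanced_accuracy[1],
               (100 * 5 / 6 + 100 * 14 / 16) / 2)
  # class c: TP 7, FN 0, FP 1, TN 14
  expect_equal(met$per_class$sensitivity[3], 100)
  expect_equal(met$per_class$specificity[3], 100 * 14 / 15)
  expect_equal(met$accuracy, 100 * 18 / 22)
  # identity confusion: everything 100%
  met2 <- classification_metrics(diag(c(4, 5, 6)))
  expect_true(all(met2$per_class$balanced_accuracy == 100))
  expect_equal(met2$accuracy, 100)
  # empty class row flagged, not averaged
  cm3 <- matrix(c(3, 0, 1, 0, 0, 0, 0, 0, 4), 3, 3, byrow = TRUE)
  met3 <- classification_metrics(cm3)
  expect_true(met3$per_class$undefined[2])
  expect_error(classification_metrics(matrix(1:6, 2, 3)), "square")
  expect_error(classification_metrics(matrix(c(1, -1, 0, 2), 2)),
               "non-negative")
})

test_that("repeated CV hits ceiling on separable data and errors sanely", {
  sep <- separable_classes(n_per_class = 30, gap = 8)
  rep <- cv_repeated(sep$x, sep$y, k = 5, n_repeats = 3, B = 10, seed = 4)
  expect_gte(rep$accuracy_mean, 99)
  expect_equal(unname(rep$per_class_mean[, "balanced_accuracy"]),
               unname((rep$per_class_mean[, "sensitivity"] +
                         rep$per_class_mean[, "specificity"]) / 2))
  expect_error(cv_repeated(sep$x, sep$y, k = nrow(sep$x) + 1), "exceeds")
  idx <- c(1:4, 31:34, 61:64)   # 4 members per class, fewer than k
  expect_error(cv_repeated(sep$x[idx, ], sep$y[idx], k = 10),
               "members per class")
})

test_that("label-permuted balanced data scores at chance", {
  set.seed(10)
  x <- matrix(rnorm(150 * 4), 150, 4)
  y <- factor(rep(c("a", "b", "c"), each = 50))
  rep <- cv_repeated(x, sample(y), k = 5, n_repeats = 4, B = 20, seed = 11)
  expect_lt(abs(rep$accuracy_mean - 100 / 3), 5)
})

test_that("longitudinal hold-out never trains on the predicted subject", {
  sep <- separable_classes(n_per_class = 20, gap = 5)
  ids <- sprintf("P%02d", seq_len(nrow(sep$x)))
  res <- longitudinal_validate(sep$x, sep$y, ids,
                               sep$x, sep$y, ids,   # follow-up = baseline
                               k = 5, n_repeats = 2, B = 10, seed = 12,
                               return_predictions = TRUE)
  expect_true(res$audit$subject_level_exclusion_ok)
  # identical inputs, same models: follow-up prediction equals the
  # subject's baseline test-fold prediction
  for (r in seq_along(res$predictions))
    expect_identical(res$predictions[[r]]$followup,
                     res$predictions[[r]]$baseline)
  expect_error(longitudinal_validate(sep$x, sep$y, ids, sep$x, sep$y,
                                     c(ids[-1], "GHOST"), k = 5,
                                     n_repeats = 1, B = 5),
               "GHOST")
})

test_that("drifted follow-up data keeps accuracy near the baseline CV", {
  cfg <- small_config(seed = 14, n_latent = 2)
  sim <- generate_cohort(cfg)
  coh <- generate_followup(sim$cohort, sim$truth, cfg)
  pb <- patient_blocks(coh)
  lv <- svd_latent_variables(cross_block_correlation(pb$Xz, pb$Yz), K = 2)
  base <- coh$data[coh$data$visit == "baseline" & coh$data$group != "control", ]
  fu <- coh$data[coh$data$visit == "followup", ]
  zx <- zscore_columns(pb$X); zy <- zscore_columns(pb$Y)
  Xf <- zscore_columns(as.matrix(fu[coh$cog_cols]), zx$stats)$block
  Yf <- zscore_columns(as.matrix(fu[coh$brain_cols]), zy$stats)$block
  sc_b <- project_scores(pb$Xz, pb$Yz, lv)
  sc_f <- project_scores(Xf, Yf, lv)
  fb <- cbind(sc_b$score_x, sc_b$score_y)
  ff <- cbind(sc_f$score_x, sc_f$score_y)
  cvrep <- cv_repeated(fb, base$group, k = 5, n_repeats = 2, B = 30,
                       seed = 15)
  longi <- longitudinal_validate(fb, base$group, base$subject_id,
                                 ff, fu$group, fu$subject_id,
                                 k = 5, n_repeats = 2, B = 30, seed = 15)
  expect_lte(abs(cvrep$accuracy_mean - longi$accuracy_mean), 10)
})

test_that("nested CV refits the PLS per fold and stays near replicate-mode accuracy", {
  cfg <- small_config(seed = 17, n_latent = 2)
  sim <- generate_cohort(cfg)
  pb <- patient_blocks(sim$cohort)
  base <- sim$cohort$data[sim$cohort$data$visit == "baseline" &
                            sim$cohort$data$group != "control", ]
  nested <- cv_repeated_nested(pb$X, pb$Y, base$group, demo = base, K = 2,
                               k = 5, n_repeats = 2, B = 20, seed = 18)
  expect_gt(nested$accuracy_mean, 100 / 3)   # beats chance
  # deterministic given the seed
  nested2 <- cv_repeated_nested(pb$X, pb$Y, base$group, demo = base, K = 2,
                                k = 5, n_repeats = 2, B = 20, seed = 18)
  expect_equal(nested$accuracy_per_repeat, nested2$accuracy_per_repeat)
  # replicate-mode (full-sample PLS) comparison: nested is the honest
  # protocol and should be in the same range, typically no higher
  lv <- svd_latent_variables(cross_block_correlation(pb$Xz, pb$Yz), K = 2)
  sc <- project_scores(pb$Xz, pb$Yz, lv)
  feats <- build_features(list(score_x = sc$score_x,
                               score_y = sc$score_y), base, "maximal")
  repl <- cv_repeated(feats, base$group, k = 5, n_repeats = 2, B = 20,
                      seed = 18)
  expect_lte(nested$accuracy_mean, repl$accuracy_mean + 15)
})

test_that("matched subsamples follow the rule and report diagnostics", {
  cfg <- small_config(seed = 16)
  coh <- generate_cohort(cfg)$cohort
  # threshold rule equals a brute-force scan
  out <- matched_subsample(coh, list(type = "threshold",
                                     column = "cdr_sumboxes", max = 0.5))
  base <- coh$data[coh$data$visit == "baseline" & coh$data$group != "control", ]
  brute <- base$subject_id[base$cdr_sumboxes < 0.5]
  kept <- out$cohort$data
  expect_setequal(kept$subject_id[kept$group != "control"], brute)
  # age matching pulls group means together
  out2 <- matched_subsample(coh, list(type = "age_match", caliper = 4))
  ages <- out2$cohort$data
  ages <- ages[ages$visit == "baseline" & ages$group != "control", ]
  means <- tapply(ages$age, droplevels(factor(ages$group)), mean)
  expect_lt(max(means) - min(means), diff(range(
    tapply(base$age, base$group, mean))) + 1e-9)
  # disjoint age ranges are infeasible
  coh2 <- coh
  coh2$data$age[coh2$data$group == "nfvPPA"] <- 200
  expect_error(matched_subsample(coh2, list(type = "age_match",
                                            caliper = 3)), "infeasible")
  expect_error(matched_subsample(coh, list(type = "nope")), "unknown")
})
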