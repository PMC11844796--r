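# Multiclass subtype prediction: bagged ensemble of pooled-covariance
# Gaussian linear discriminant learners, majority vote, repeated stratified
# k-fold CV, per-class one-vs-rest metrics, longitudinal hold-out with
# subject-level exclusion, matched subsamples.

# Fit one pooled-covariance Gaussian LDA on (x, y). A small ridge
# (1e-6 * trace/p, escalated tenfold if needed) keeps the pooled covariance
# invertible on small bootstrap folds.
lda_fit <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x); y <- factor(y)
  classes <- levels(y)
  p <- ncol(x); n <- nrow(x)
  vm <- vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
               numeric(p))
  mu <- if (p == 1) matrix(vm, ncol = 1) else t(vm)
  centered <- x - mu[as.integer(y), , drop = FALSE]
  S <- crossprod(centered) / max(n - length(classes), 1)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    lambda <- ridge * sum(diag(S)) / p
    if (lambda <= 0) lambda <- ridge
    for (i in 0:8) {
      ch <- tryCatch(chol(S + diag(lambda * 10^i, p)),
                     error = function(e) NULL)
      if (!is.null(ch)) break
    }
    if (is.null(ch))
      stop("pooled covariance singular even after ridge escalation")
  }
  Sinv <- chol2inv(ch)
  A <- Sinv %*% t(mu)                              # p x C
  const <- -0.5 * colSums(t(mu) * A) + log(as.numeric(table(y)[classes]) / n)
  list(A = A, const = const, classes = classes)
}

# n x C matrix of discriminant scores (log-posterior up to a constant).
lda_scores <- function(fit, x) {
  s <- as.matrix(x) %*% fit$A
  sweep(s, 2, fit$const, "+")
}

#' Fit a bagged ensemble of linear discriminant learners
#'
#' Trains B pooled-covariance Gaussian linear discriminant classifiers,
#' each on an independent with-replacement resample of the training rows
#' (bootstrap aggregation). Resamples missing a class are redrawn.
#'
#' @param features Numeric matrix (subjects x features).
#' @param labels Class labels; >= 2 classes with >= 2 members each.
#' @param B Number of learners (default 100).
#' @param seed Integer seed; fitting is deterministic given it.
#' @param resample If \code{FALSE}, every learner sees the full training
#'   set (so B = 1 reproduces a single discriminant classifier).
#' @param ridge Ridge coefficient for near-singular pooled covariances.
#' @param max_retries Redraw limit for class-deficient bootstrap samples.
#' @return Object of class \code{"ftd_ensemble"}.
#' @export
fit_ensemble <- function(features, labels, B = 100, seed = 1L,
                         resample = TRUE, ridge = 1e-6, max_retries = 100) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("non-finite feature values")
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2))
    stop("every class needs at least 2 training members, got: ",
         paste(names(which(table(labels) < 2)), collapse = ", "))
  n <- nrow(features)
  learners <- vector("list", B)
  boot_idx <- vector("list", B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      if (resample) {
        for (try in seq_len(max_retries + 1)) {
          idx <- sample.int(n, n, replace = TRUE)
          if (nlevels(droplevels(labels[idx])) == nlevels(labels) &&
              all(table(labels[idx]) >= 2)) break
          if (try > max_retries)
            stop("bootstrap draw missing a class after ", max_retries,
                 " redraws")
        }
      } else idx <- seq_len(n)
      boot_idx[[b]] <- idx
      learners[[b]] <- lda_fit(features[idx, , drop = FALSE], labels[idx],
                               ridge = ridge)
    }
  })
  structure(list(learners = learners, boot_idx = boot_idx,
                 classes = levels(labels), p = ncol(features),
                 feature_names = colnames(features), seed = seed),
            class = "ftd_ensemble")
}

#' Majority-vote prediction from a bagged ensemble
#'
#' Each learner votes for its most probable class; the modal label wins.
#' Ties are broken by the highest mean class posterior across learners,
#' then by lexicographic class order.
#'
#' @param model A \code{\link{fit_ensemble}} result.
#' @param features Numeric matrix with the training feature columns.
#' @return Character vector of predicted labels.
#' @export
predict_majority <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$p)
    stop("feature column count does not match the ensemble (", model$p, ")")
  if (!is.null(model$feature_names) && !is.null(colnames(features)) &&
      !identical(colnames(features), model$feature_names))
    stop("feature columns do not match the ensemble: expected ",
         paste(model$feature_names, collapse = ", "))
  n <- nrow(features); C <- length(model$classes)
  votes <- matrix(0L, n, C, dimnames = list(NULL, model$classes))
  post_sum <- matrix(0, n, C, dimnames = list(NULL, model$classes))
  for (lr in model$learners) {
    sc <- lda_scores(lr, features)
    # softmax for posterior averaging (numerically stabilized)
    m <- apply(sc, 1, max)
    pr <- exp(sc - m)
    pr <- pr / rowSums(pr)
    pick <- max.col(sc, ties.method = "first")
    ci <- match(lr$classes, model$classes)
    for (j in seq_along(ci)) post_sum[, ci[j]] <- post_sum[, ci[j]] + pr[, j]
    win <- ci[pick]
    votes[cbind(seq_len(n), win)] <- votes[cbind(seq_len(n), win)] + 1L
  }
  out <- character(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      best <- top[post_sum[i, top] == max(post_sum[i, top])]
      top <- best[order(model$classes[best])][1]
    }
    out[i] <- model$classes[top]
  }
  out
}

#' @export
predict.ftd_ensemble <- function(object, newdata, ...) {
  predict_majority(object, newdata)
}

# Stratified k-fold assignment: per class, shuffled indices dealt round-robin.
stratified_folds <- function(labels, k) {
  labels <- factor(labels)
  if (any(table(labels) < k))
    stop("stratified ", k, "-fold CV needs >= ", k, " members per class; ",
         "reduce k or merge rare classes")
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Per-class classification metrics from a confusion matrix
#'
#' One-vs-rest sensitivity TP/(TP+FN), specificity TN/(TN+FP), balanced
#' accuracy (their mean) per class, and overall accuracy (trace/total).
#' All rates are percentages. Classes with no true members have undefined
#' sensitivity; they are flagged and excluded from averages.
#'
#' @param cm Square confusion matrix, rows = true class, columns =
#'   predicted class.
#' @return List with \code{per_class} data.frame (class, sensitivity,
#'   specificity, balanced_accuracy, undefined) and \code{accuracy}.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0) || any(cm != round(cm)))
    stop("confusion matrix must hold non-negative integer counts")
  total <- sum(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  per <- lapply(seq_len(nrow(cm)), function(c) {
    tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp; tn <- total - tp - fn - fp
    sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    data.frame(class = classes[c], sensitivity = sens, specificity = spec,
               balanced_accuracy = (sens + spec) / 2,
               undefined = is.na(sens) || is.na(spec))
  })
  list(per_class = do.call(rbind, per),
       accuracy = 100 * sum(diag(cm)) / total)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each of \code{n_repeats} randomized splits, a fresh stratified
#' k-fold partition is drawn; per fold an ensemble is fit on the training
#' rows and evaluated on the held-out rows. Accuracy is aggregated per
#' repeat (pooled over folds); the report carries mean and SD over repeats
#' plus per-class one-vs-rest sensitivity/specificity/balanced accuracy.
#'
#' @param features,labels Training data.
#' @param k Folds (default 10).
#' @param n_repeats Randomized repeats (default 100).
#' @param B Learners per ensemble.
#' @param seed Integer seed (repeat r uses \code{seed + r}).
#' @param resample Passed to \code{\link{fit_ensemble}}.
#' @return Object of class \code{"classifier_report"}.
#' @export
cv_repeated <- function(features, labels, k = 10, n_repeats = 100, B = 100,
                        seed = 1L, resample = TRUE) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  n <- nrow(features)
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  classes <- levels(labels)
  acc <- numeric(n_repeats)
  per_class <- array(NA_real_, c(n_repeats, length(classes), 3),
                     dimnames = list(NULL, classes,
                                     c("sensitivity", "specificity",
                                       "balanced_accuracy")))
  cm_sum <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (r in seq_len(n_repeats)) {
    fold <- with_seed(seed + r, stratified_folds(labels, k))
    pred <- character(n)
    for (f in seq_len(k)) {
      test <- fold == f
      model <- fit_ensemble(features[!test, , drop = FALSE], labels[!test],
                            B = B, seed = seed + r * 1000L + f,
                            resample = resample)
      pred[test] <- predict_majority(model, features[test, , drop = FALSE])
    }
    cm <- table(factor(labels, classes), factor(pred, classes))
    met <- classification_metrics(cm)
    acc[r] <- met$accuracy
    for (j in seq_along(classes))
      per_class[r, j, ] <- unlist(met$per_class[j, c("sensitivity",
                                                     "specificity",
                                                     "balanced_accuracy")])
    cm_sum <- cm_sum + cm
  }
  structure(list(
    accuracy_per_repeat = acc,
    accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
    per_class_mean = apply(per_class, c(2, 3), mean, na.rm = TRUE),
    per_class_sd = apply(per_class, c(2, 3), stats::sd, na.rm = TRUE),
    confusion = cm_sum, n_repeats = n_repeats, k = k, B = B, seed = seed,
    protocol = sprintf("stratified %d-fold x %d repeats, B = %d", k,
                       n_repeats, B)),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Classification report (", x$protocol, ")\n", sep = "")
  cat(sprintf("  accuracy: %.2f%% (SD = %.2f%%)\n",
              x$accuracy_mean, if (is.na(x$accuracy_sd)) 0 else x$accuracy_sd))
  m <- x$per_class_mean
  for (cl in rownames(m))
    cat(sprintf("  %-8s sens %.2f%%  spec %.2f%%  balanced %.2f%%\n", cl,
                m[cl, "sensitivity"], m[cl, "specificity"],
                m[cl, "balanced_accuracy"]))
  invisible(x)
}

#' Repeated CV with the PLS nested inside each training fold
#'
#' The default protocol fits the (unsupervised) PLS once on all baseline
#' patients and cross-validates only the classifier, mirroring how such
#' pipelines are usually run; full-sample PLS is nonetheless a mild form
#' of leakage because test subjects influence the saliences and the
#' standardization. In nested mode the z-scoring and the cross-block SVD
#' are refit on each training fold alone and held-out subjects are pure
#' projections.
#'
#' @param X,Y Raw cognition and brain blocks (subjects x variables).
#' @param labels Class labels.
#' @param demo Optional data.frame with age, sex, education appended as
#'   covariate features.
#' @param K Number of LVs to retain in each training-fold PLS.
#' @param k,n_repeats,B,seed As in \code{\link{cv_repeated}}.
#' @return A \code{classifier_report}.
#' @export
cv_repeated_nested <- function(X, Y, labels, demo = NULL, K = 4,
                               k = 10, n_repeats = 10, B = 100, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  labels <- droplevels(factor(labels))
  classes <- levels(labels)
  n <- nrow(X)
  acc <- numeric(n_repeats)
  cm_sum <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  per_class <- array(NA_real_, c(n_repeats, length(classes), 3),
                     dimnames = list(NULL, classes,
                                     c("sensitivity", "specificity",
                                       "balanced_accuracy")))
  covs <- function(d) if (is.null(d)) NULL else
    cbind(age = d$age, sex = as.numeric(d$sex == "M"),
          education = d$education)
  for (r in seq_len(n_repeats)) {
    fold <- with_seed(seed + r, stratified_folds(labels, k))
    pred <- character(n)
    for (f in seq_len(k)) {
      test <- fold == f
      zx <- zscore_columns(X[!test, , drop = FALSE])
      zy <- zscore_columns(Y[!test, , drop = FALSE])
      lv <- svd_latent_variables(cross_block_correlation(zx$block,
                                                         zy$block),
                                 K = K)
      tr <- project_scores(zx$block, zy$block, lv)
      te <- project_scores(zscore_columns(X[test, , drop = FALSE],
                                          zx$stats)$block,
                           zscore_columns(Y[test, , drop = FALSE],
                                          zy$stats)$block, lv)
      f_tr <- cbind(tr$score_x, tr$score_y)
      f_te <- cbind(te$score_x, te$score_y)
      if (!is.null(demo)) {
        f_tr <- cbind(f_tr, covs(demo[!test, , drop = FALSE]))
        f_te <- cbind(f_te, covs(demo[test, , drop = FALSE]))
      }
      colnames(f_te) <- colnames(f_tr)
      model <- fit_ensemble(f_tr, labels[!test], B = B,
                            seed = seed + r * 1000L + f)
      pred[test] <- predict_majority(model, f_te)
    }
    cm <- table(factor(labels, classes), factor(pred, classes))
    met <- classification_metrics(cm)
    acc[r] <- met$accuracy
    for (j in seq_along(classes))
      per_class[r, j, ] <- unlist(met$per_class[j, c("sensitivity",
                                                     "specificity",
                                                     "balanced_accuracy")])
    cm_sum <- cm_sum + cm
  }
  structure(list(
    accuracy_per_repeat = acc,
    accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
    per_class_mean = apply(per_class, c(2, 3), mean, na.rm = TRUE),
    per_class_sd = apply(per_class, c(2, 3), stats::sd, na.rm = TRUE),
    confusion = cm_sum, n_repeats = n_repeats, k = k, B = B, seed = seed,
    protocol = sprintf(
      "nested PLS, stratified %d-fold x %d repeats, B = %d, K = %d",
      k, n_repeats, B, K)),
    class = "classifier_report")
}

#' Longitudinal hold-out validation
#'
#' Baseline rows form the training pool; follow-up rows are test-only.
#' Within each repeat's stratified k-fold partition of the baseline
#' subjects, a follow-up row is predicted exclusively by the ensemble whose
#' training folds exclude that subject's baseline row (subject-level
#' exclusion). Follow-up features must already be standardized with
#' baseline statistics upstream.
#'
#' @param base_features,base_labels Baseline training data.
#' @param fu_features,fu_labels Follow-up test data.
#' @param base_subjects,fu_subjects Subject ids aligning the two sets;
#'   every follow-up subject must have a baseline row.
#' @param k,n_repeats,B,seed As in \code{\link{cv_repeated}}.
#' @param return_predictions Also return per-repeat baseline test-fold and
#'   follow-up predictions (for audit).
#' @return A \code{classifier_report} over the follow-up predictions, with
#'   an \code{audit} element recording that no training fold contained a
#'   predicted subject's baseline row.
#' @export
longitudinal_validate <- function(base_features, base_labels, base_subjects,
                                  fu_features, fu_labels, fu_subjects,
                                  k = 10, n_repeats = 100, B = 100,
                                  seed = 1L, return_predictions = FALSE) {
  base_features <- as.matrix(base_features)
  fu_features <- as.matrix(fu_features)
  base_labels <- droplevels(factor(base_labels))
  classes <- levels(base_labels)
  orphan <- setdiff(fu_subjects, base_subjects)
  if (length(orphan))
    stop("follow-up subjects missing from baseline: ",
         paste(orphan, collapse = ", "))
  if (anyDuplicated(base_subjects)) stop("duplicated baseline subjects")
  n <- nrow(base_features)
  acc <- numeric(n_repeats)
  per_class <- array(NA_real_, c(n_repeats, length(classes), 3),
                     dimnames = list(NULL, classes,
                                     c("sensitivity", "specificity",
                                       "balanced_accuracy")))
  cm_sum <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  audit_ok <- TRUE
  preds <- if (return_predictions) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    fold <- with_seed(seed + r, stratified_folds(base_labels, k))
    fu_pred <- rep(NA_character_, length(fu_subjects))
    base_pred <- rep(NA_character_, n)
    for (f in seq_len(k)) {
      test <- fold == f
      model <- fit_ensemble(base_features[!test, , drop = FALSE],
                            base_labels[!test], B = B,
                            seed = seed + r * 1000L + f)
      base_pred[test] <- predict_majority(
        model, base_features[test, , drop = FALSE])
      fu_in_fold <- fu_subjects %in% base_subjects[test]
      if (any(fu_in_fold)) {
        if (any(fu_subjects[fu_in_fold] %in% base_subjects[!test]))
          audit_ok <- FALSE
        fu_pred[fu_in_fold] <- predict_majority(
          model, fu_features[fu_in_fold, , drop = FALSE])
      }
    }
    cm <- table(factor(fu_labels, classes), factor(fu_pred, classes))
    met <- classification_metrics(cm)
    acc[r] <- met$accuracy
    for (j in seq_along(classes))
      per_class[r, j, ] <- unlist(met$per_class[j, c("sensitivity",
                                                     "specificity",
                                                     "balanced_accuracy")])
    cm_sum <- cm_sum + cm
    if (return_predictions)
      preds[[r]] <- list(baseline = stats::setNames(base_pred, base_subjects),
                         followup = stats::setNames(fu_pred, fu_subjects))
  }
  structure(list(
    accuracy_per_repeat = acc,
    accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
    per_class_mean = apply(per_class, c(2, 3), mean, na.rm = TRUE),
    per_class_sd = apply(per_class, c(2, 3), stats::sd, na.rm = TRUE),
    confusion = cm_sum, n_repeats = n_repeats, k = k, B = B, seed = seed,
    audit = list(subject_level_exclusion_ok = audit_ok),
    predictions = preds,
    protocol = sprintf(
      "longitudinal hold-out, stratified %d-fold x %d repeats, B = %d",
      k, n_repeats, B)),
    class = "classifier_report")
}

#' Matched or filtered subsamples for validation
#'
#' Either filters rows by a threshold rule (e.g. disease severity,
#' CDR sum of boxes < 1.5) or builds an age-matched subset by greedy
#' nearest-age selection without replacement: the smallest group is the
#' reference and, for each of its members, the closest-aged unused member
#' of every other group (within \code{caliper} years) joins the subset.
#'
#' @param cohort A \code{\link{cohort}} (baseline patient rows are used).
#' @param rule List: \code{list(type = "threshold", column =, max =)} or
#'   \code{list(type = "age_match", caliper = 5)}.
#' @return List with the subset \code{cohort} and a \code{report} of
#'   achieved per-group means.
#' @export
matched_subsample <- function(cohort, rule) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  keep_base <- d$visit == "baseline" & d$group != "control"
  base <- d[keep_base, ]
  if (identical(rule$type, "threshold")) {
    if (!rule$column %in% names(base)) stop("unknown column: ", rule$column)
    sel <- base$subject_id[!is.na(base[[rule$column]]) &
                             base[[rule$column]] < rule$max]
  } else if (identical(rule$type, "age_match")) {
    caliper <- if (is.null(rule$caliper)) 5 else rule$caliper
    groups <- split(base[, c("subject_id", "age")], base$group)
    groups <- groups[order(vapply(groups, nrow, 1L))]
    ref <- groups[[1]]
    used <- lapply(groups[-1], function(g) rep(FALSE, nrow(g)))
    sel <- character(0)
    for (i in seq_len(nrow(ref))) {
      picks <- ref$subject_id[i]
      ok <- TRUE
      chosen <- integer(length(used))
      for (j in seq_along(used)) {
        g <- groups[[j + 1]]
        cand <- which(!used[[j]] & abs(g$age - ref$age[i]) <= caliper)
        if (!length(cand)) { ok <- FALSE; break }
        pick <- cand[which.min(abs(g$age[cand] - ref$age[i]))]
        chosen[j] <- pick
        picks <- c(picks, g$subject_id[pick])
      }
      if (ok) {
        for (j in seq_along(used)) used[[j]][chosen[j]] <- TRUE
        sel <- c(sel, picks)
      }
    }
    if (!length(sel))
      stop("age matching infeasible: no cross-group matches within ",
           caliper, " years (age ranges may be disjoint)")
  } else stop("unknown matching rule type: ", rule$type)
  out <- cohort
  out$data <- d[d$subject_id %in% sel | d$group == "control", ]
  achieved <- stats::aggregate(age ~ group,
                               out$data[out$data$visit == "baseline" &
                                          out$data$group != "control", ],
                               function(a) c(mean = mean(a), sd = stats::sd(a),
                                             n = length(a)))
  list(cohort = out, report = achieved)
}
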