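# Two-block behavioural PLS: SVD of the cross-block correlation matrix,
# covariance-explained accounting, permutation significance, bootstrap
# ratios with confidence-interval thresholding, subject projection scores.

#' Cross-block correlation matrix
#'
#' For z-scored blocks Xz (n x p_x) and Yz (n x p_y), computes
#' R = Xz' Yz / (n - 1), whose entries are the pairwise Pearson
#' correlations between cognition and brain variables.
#'
#' @param Xz,Yz Column-standardized numeric matrices with equal row counts
#'   (n >= 3).
#' @return Object of class \code{"cross_block"}: list with \code{R}
#'   (p_x x p_y) and \code{n}.
#' @export
cross_block_correlation <- function(Xz, Yz) {
  Xz <- as.matrix(Xz); Yz <- as.matrix(Yz)
  if (nrow(Xz) != nrow(Yz))
    stop("Xz and Yz must have the same number of rows")
  n <- nrow(Xz)
  if (n < 3) stop("need at least 3 subjects")
  R <- crossprod(Xz, Yz) / (n - 1)
  structure(list(R = R, n = n), class = "cross_block")
}

#' Singular value decomposition of the cross-block matrix
#'
#' Decomposes R = U diag(d) V' into orthogonal latent variables (LVs).
#' Covariance explained per LV is d_k^2 / sum(d^2), computed over the full
#' rank before any truncation; it serves as the LV's effect size. Singular
#' vectors are sign-fixed so each LV's largest-magnitude combined loading
#' is positive.
#'
#' @param R A \code{cross_block} object (or bare matrix).
#' @param K Optional number of LVs to retain; truncation never alters the
#'   stored covariance-explained fractions.
#' @return Object of class \code{"lv_set"}: U, V, d, covexp, K.
#' @export
svd_latent_variables <- function(R, K = NULL) {
  M <- if (inherits(R, "cross_block")) R$R else as.matrix(R)
  if (any(!is.finite(M))) stop("non-finite entries in cross-block matrix")
  s <- svd(M)
  d <- s$d
  covexp <- d^2 / sum(d^2)
  U <- s$u; V <- s$v
  for (k in seq_along(d)) {           # deterministic sign convention
    w <- c(U[, k], V[, k])
    i <- which.max(abs(w))
    if (w[i] < 0) { U[, k] <- -U[, k]; V[, k] <- -V[, k] }
  }
  rownames(U) <- rownames(M); rownames(V) <- colnames(M)
  full_rank <- length(d)
  if (!is.null(K)) {
    K <- min(K, full_rank)
    U <- U[, seq_len(K), drop = FALSE]
    V <- V[, seq_len(K), drop = FALSE]
    d <- d[seq_len(K)]
  } else K <- full_rank
  structure(list(U = U, V = V, d = d, covexp = covexp, K = K,
                 full_rank = full_rank), class = "lv_set")
}

#' @export
print.lv_set <- function(x, ...) {
  cat("Latent variable set:", x$K, "LV(s) retained of rank", x$full_rank, "\n")
  df <- data.frame(LV = seq_len(x$K), d = x$d,
                   covexp_pct = 100 * x$covexp[seq_len(x$K)])
  if (!is.null(x$perm_p)) df$perm_p <- x$perm_p[seq_len(x$K)]
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Permutation test for latent variables
#'
#' Rows of Xz are randomly permuted (default 500 times), the cross-block
#' correlation and its SVD recomputed each time, building a null
#' distribution of singular values compared rank-to-rank. P-values use the
#' add-one convention p = (1 + #\{d_perm >= d_obs\}) / (n_perm + 1), so a
#' finite number of permutations never certifies p = 0.
#'
#' @param Xz,Yz Z-scored blocks as in \code{\link{cross_block_correlation}}.
#' @param n_perm Number of permutations (>= 1; 500 by default).
#' @param seed Integer seed.
#' @param statistic \code{"singular"} compares singular values rank-to-rank
#'   (default); \code{"covexp"} compares covariance-explained fractions.
#' @return Numeric vector of per-LV p-values.
#' @export
permutation_pvalues <- function(Xz, Yz, n_perm = 500, seed = 1L,
                                statistic = c("singular", "covexp")) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- svd_latent_variables(cross_block_correlation(Xz, Yz))
  stat_of <- function(lv) if (statistic == "singular") lv$d else lv$covexp
  d_obs <- stat_of(obs)
  n <- nrow(Xz)
  exceed <- numeric(length(d_obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      dp <- stat_of(svd_latent_variables(
        cross_block_correlation(Xz[perm, , drop = FALSE], Yz)))
      exceed <- exceed + (dp >= d_obs)
    }
  })
  (1 + exceed) / (n_perm + 1)
}

#' Bootstrap ratios for salience weights
#'
#' Subjects are resampled with replacement jointly across blocks (default
#' 500 times); each resample is re-standardized, its cross-block SVD
#' recomputed, and each LV sign-aligned to the original solution by the
#' sign of the dot product of the concatenated [u; v] with the original.
#' The bootstrap ratio (BSR) of a variable is its original salience weight
#' divided by the bootstrap standard error of that weight.
#'
#' @param Xz,Yz Z-scored blocks that produced \code{lvset}.
#' @param lvset \code{lv_set} from \code{\link{svd_latent_variables}}.
#' @param n_boot Number of bootstrap resamples (>= 2; 500 by default).
#' @param seed Integer seed.
#' @param stratify Optional factor (e.g. diagnostic group) for stratified
#'   resampling; default unstratified.
#' @param max_retries Redraw limit for resamples with a zero-variance
#'   column.
#' @return List with \code{bsr_x}, \code{bsr_y} (salience / bootstrap SE),
#'   and \code{se_x}, \code{se_y}.
#' @export
bootstrap_ratios <- function(Xz, Yz, lvset, n_boot = 500, seed = 1L,
                             stratify = NULL, max_retries = 100) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  Xz <- as.matrix(Xz); Yz <- as.matrix(Yz)
  n <- nrow(Xz); K <- lvset$K
  draw <- function() {
    if (is.null(stratify)) sample.int(n, n, replace = TRUE)
    else unlist(lapply(split(seq_len(n), stratify),
                       function(i) sample(i, length(i), replace = TRUE)),
                use.names = FALSE)
  }
  Ub <- array(NA_real_, c(nrow(lvset$U), K, n_boot))
  Vb <- array(NA_real_, c(nrow(lvset$V), K, n_boot))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (try in seq_len(max_retries + 1)) {
        idx <- draw()
        Xb <- Xz[idx, , drop = FALSE]; Yb <- Yz[idx, , drop = FALSE]
        sx <- apply(Xb, 2, stats::sd); sy <- apply(Yb, 2, stats::sd)
        if (all(sx > 0) && all(sy > 0)) break
        if (try > max_retries)
          stop("bootstrap resampling: zero-variance column after ",
               max_retries, " redraws")
      }
      lvb <- svd_latent_variables(cross_block_correlation(
        zscore_columns(Xb)$block, zscore_columns(Yb)$block), K = K)
      for (k in seq_len(K)) {
        s <- sum(c(lvb$U[, k], lvb$V[, k]) * c(lvset$U[, k], lvset$V[, k]))
        sgn <- if (s < 0) -1 else 1
        Ub[, k, b] <- sgn * lvb$U[, k]
        Vb[, k, b] <- sgn * lvb$V[, k]
      }
    }
  })
  se_x <- apply(Ub, c(1, 2), stats::sd)
  se_y <- apply(Vb, c(1, 2), stats::sd)
  dimnames(se_x) <- dimnames(lvset$U)
  dimnames(se_y) <- dimnames(lvset$V)
  list(bsr_x = lvset$U / se_x, bsr_y = lvset$V / se_y,
       se_x = se_x, se_y = se_y)
}

#' Threshold bootstrap ratios at a confidence level
#'
#' A variable contributes reliably to an LV when |BSR| meets the normal
#' quantile of the two-sided (1 - alpha) confidence criterion
#' (1.959964 at alpha = 0.05).
#'
#' @param bsr Matrix (or vector) of bootstrap ratios.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Logical mask of the same shape.
#' @export
threshold_bsr <- function(bsr, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(!is.finite(bsr))) stop("non-finite bootstrap ratios")
  abs(bsr) >= stats::qnorm(1 - alpha / 2)
}

#' Subject projection scores
#'
#' Projects data rows onto the saliences: the cognition-block score of a
#' subject is its (standardized) cognition row times U, and the brain-block
#' score its brain row times V. Follow-up rows standardized with baseline
#' statistics can be projected the same way.
#'
#' @param X_rows,Y_rows Standardized rows, columns matching the blocks that
#'   produced \code{lvset}.
#' @param lvset \code{lv_set}.
#' @return Object of class \code{"subject_scores"}: \code{score_x},
#'   \code{score_y} (n x K matrices, subject ids preserved as rownames).
#' @export
project_scores <- function(X_rows, Y_rows, lvset) {
  X_rows <- as.matrix(X_rows); Y_rows <- as.matrix(Y_rows)
  if (ncol(X_rows) != nrow(lvset$U))
    stop("X_rows column count does not match the cognition saliences")
  if (ncol(Y_rows) != nrow(lvset$V))
    stop("Y_rows column count does not match the brain saliences")
  structure(list(score_x = X_rows %*% lvset$U,
                 score_y = Y_rows %*% lvset$V),
            class = "subject_scores")
}

#' Fit the full behavioural PLS
#'
#' Convenience wrapper: z-scores the raw blocks (self mode), computes the
#' cross-block correlation and its SVD, permutation p-values, bootstrap
#' ratios with CI thresholding, and subject projection scores. The number
#' of retained LVs is the count of permutation p < alpha (unadjusted).
#'
#' @param X,Y Raw cognition and brain blocks (subjects x variables).
#' @param n_perm,n_boot Permutation / bootstrap repetition counts.
#' @param alpha Significance level for LV retention and BSR thresholding.
#' @param seed Integer seed (permutations use \code{seed}, bootstraps
#'   \code{seed + 1}).
#' @param statistic Permutation statistic, see
#'   \code{\link{permutation_pvalues}}.
#' @param stratify Optional stratification factor for the bootstrap.
#' @return Object of class \code{"pls_fit"}: the \code{lv_set} enriched
#'   with \code{perm_p}, \code{bsr_x/y}, \code{sig_mask_x/y}, subject
#'   scores, and the standardization stats of both blocks.
#' @export
pls_fit <- function(X, Y, n_perm = 500, n_boot = 500, alpha = 0.05,
                    seed = 1L, statistic = "singular", stratify = NULL) {
  zx <- zscore_columns(X); zy <- zscore_columns(Y)
  lv_full <- svd_latent_variables(cross_block_correlation(zx$block, zy$block))
  perm_p <- permutation_pvalues(zx$block, zy$block, n_perm = n_perm,
                                seed = seed, statistic = statistic)
  K <- max(1L, sum(perm_p < alpha))
  lv <- svd_latent_variables(cross_block_correlation(zx$block, zy$block),
                             K = K)
  bs <- bootstrap_ratios(zx$block, zy$block, lv, n_boot = n_boot,
                         seed = seed + 1L, stratify = stratify)
  scores <- project_scores(zx$block, zy$block, lv)
  structure(c(lv, list(
    perm_p = perm_p, n_perm = n_perm, n_boot = n_boot, alpha = alpha,
    seed = seed,
    bsr_x = bs$bsr_x, bsr_y = bs$bsr_y,
    sig_mask_x = threshold_bsr(bs$bsr_x, alpha),
    sig_mask_y = threshold_bsr(bs$bsr_y, alpha),
    score_x = scores$score_x, score_y = scores$score_y,
    stats_x = zx$stats, stats_y = zy$stats)),
    class = c("pls_fit", "lv_set"))
}
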