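# Longitudinal rate-of-change statistics on LV scores: yearly rates,
# within-cohort paired change tests, between-variant rate contrasts with
# Tukey-Kramer correction.

#' Yearly rate of change
#'
#' \code{(followup - baseline) / interval_years}; vectorized over records.
#'
#' @param baseline,followup Scores at the two visits.
#' @param interval_years Positive visit spacing in years.
#' @return Rates in score units per year.
#' @export
yearly_rate <- function(baseline, followup, interval_years) {
  if (any(interval_years <= 0))
    stop("interval_years must be > 0")
  (followup - baseline) / interval_years
}

#' Build rate records from baseline and follow-up subject scores
#'
#' Joins the two visits by subject id (pairing is enforced by key, never by
#' row order), and computes the yearly rate for every LV and block.
#'
#' @param scores_base,scores_fu \code{subject_scores} with subject ids as
#'   rownames.
#' @param interval_years Named vector (by follow-up subject id) of visit
#'   spacings.
#' @return data.frame with subject_id, lv, block, baseline, followup,
#'   interval, rate.
#' @export
rate_records <- function(scores_base, scores_fu, interval_years) {
  subj_fu <- rownames(scores_fu$score_x)
  subj_base <- rownames(scores_base$score_x)
  if (is.null(subj_fu) || is.null(subj_base))
    stop("subject ids (rownames) required on both score sets")
  missing <- setdiff(subj_fu, subj_base)
  if (length(missing))
    stop("follow-up subjects without baseline scores: ",
         paste(missing, collapse = ", "))
  if (is.null(names(interval_years)) ||
      !all(subj_fu %in% names(interval_years)))
    stop("interval_years must be named by follow-up subject id")
  K <- ncol(scores_base$score_x)
  out <- list()
  for (block in c("score_x", "score_y")) {
    b <- scores_base[[block]][subj_fu, , drop = FALSE]
    f <- scores_fu[[block]]
    for (k in seq_len(K)) {
      iv <- interval_years[subj_fu]
      out[[paste(block, k)]] <- data.frame(
        subject_id = subj_fu, lv = k, block = block,
        baseline = b[, k], followup = f[, k], interval = unname(iv),
        rate = yearly_rate(b[, k], f[, k], iv))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired within-cohort change test
#'
#' Two-sided paired t-test on follow-up minus baseline scores.
#'
#' @param baseline,followup Paired score vectors (same subjects, same
#'   order; use \code{\link{rate_records}} to align by id).
#' @return List with \code{t}, \code{p}, \code{n}, and
#'   \code{degenerate} = TRUE when the differences have zero variance
#'   (p undefined).
#' @export
paired_change_test <- function(baseline, followup) {
  if (length(baseline) != length(followup))
    stop("baseline and followup must have equal length")
  n <- length(baseline)
  if (n < 2) stop("need at least 2 pairs")
  diffs <- followup - baseline
  if (stats::sd(diffs) <= 1e-12 * max(1, abs(mean(diffs)))) {
    # no change at all is a definite null result; a non-zero constant
    # shift has an undefined p (zero variance) and is only flagged
    if (all(diffs == 0))
      return(list(t = 0, p = 1, n = n, degenerate = TRUE))
    return(list(t = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(followup, baseline, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, n = n, degenerate = FALSE)
}

#' Between-variant rate contrasts with Tukey-Kramer correction
#'
#' All pairwise two-sample t-statistics on yearly rates, with familywise
#' adjustment by the Tukey-Kramer studentized-range procedure (pooled
#' within-group variance across all groups, df = N - g), which accommodates
#' unequal group sizes. Welch t-statistics are available by flag (the
#' Tukey p-values always use the classical pooled variance).
#'
#' @param rates Numeric vector of yearly rates.
#' @param groups Group labels (>= 2 groups with >= 2 members each).
#' @param welch Use Welch (unequal-variance) pairwise t-statistics.
#' @return data.frame: contrast, tStat, p_tukey, n1, n2.
#' @export
group_rate_contrasts <- function(rates, groups, welch = FALSE) {
  groups <- droplevels(factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("degenerate group sizes (need >= 2 per group): ",
         paste(names(which(sizes < 2)), collapse = ", "))
  g <- length(lev); N <- length(rates)
  means <- tapply(rates, groups, mean)
  mse <- sum(tapply(rates, groups,
                    function(x) sum((x - mean(x))^2))) / (N - g)
  df <- N - g
  out <- list()
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    a <- lev[i]; b <- lev[j]
    xa <- rates[groups == a]; xb <- rates[groups == b]
    na <- length(xa); nb <- length(xb)
    if (welch) {
      tt <- stats::t.test(xa, xb)
      tstat <- unname(tt$statistic)
    } else {
      sp2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) /
        (na + nb - 2)
      tstat <- (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
    }
    q <- abs(means[[a]] - means[[b]]) /
      sqrt(mse / 2 * (1 / na + 1 / nb))
    p <- stats::ptukey(q, nmeans = g, df = df, lower.tail = FALSE)
    out[[paste(a, b)]] <- data.frame(
      contrast = paste(a, "vs", b), tStat = tstat, p_tukey = p,
      n1 = na, n2 = nb)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
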