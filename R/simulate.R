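# Synthetic cohort generation: planted low-rank brain-cognition structure,
# group separations, demographic confounds, controls, follow-up visits.

#' Sparse orthonormal salience matrix
#'
#' Draws a p x K matrix whose columns are unit-norm, mutually orthogonal,
#' and have a `sparsity` fraction of exactly-zero entries (zero positions
#' chosen uniformly at random per column). Orthogonality is enforced by
#' alternating support-preserving projections, so the zero pattern of each
#' column survives.
#'
#' @param p Number of variables.
#' @param K Number of columns (planted LVs).
#' @param sparsity Fraction of zero loadings per column, in [0, 1).
#' @return p x K matrix with orthonormal, sparse columns.
#' @keywords internal
sparse_orthonormal <- function(p, K, sparsity) {
  if (K == 0) return(matrix(numeric(0), p, 0))
  n_zero <- floor(sparsity * p)
  if (p - n_zero < K)
    stop("sparsity too high: fewer than K non-zero loadings per column")
  # equal-magnitude random-sign loadings on a random support: identifiable
  # under column standardization (all non-zero columns share one scale)
  M <- matrix(sample(c(-1, 1), p * K, replace = TRUE), p, K)
  for (k in seq_len(K))
    M[sample.int(p, n_zero), k] <- 0
  if (K > 1) {
    for (iter in 1:500) {
      for (k in 2:K) for (j in 1:(k - 1)) {
        cp <- sum(M[, j] * M[, k])               # lives on the common support
        common <- M[, j] != 0 & M[, k] != 0
        denom <- sum(M[common, j]^2)
        if (denom > 1e-12) M[common, k] <- M[common, k] - (cp / denom) * M[common, j]
      }
      G <- crossprod(M)
      off <- max(abs(G[upper.tri(G)]))
      if (off < 1e-12 * max(diag(G))) break
      if (iter == 500)
        stop("sparse orthonormalization failed to converge; ",
             "try a lower sparsity or different seed")
    }
  }
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_len(K)) {
    i <- which.max(abs(M[, k]))
    if (M[i, k] < 0) M[, k] <- -M[, k]
  }
  M
}

# Truncated normal >= lower, by resampling.
rtrunc_norm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
  }
  x
}

# Demographic covariates for one group.
draw_demographics <- function(n, group, config) {
  data.frame(
    age = rnorm(n, config$age_mean[[group]], config$age_sd[[group]]),
    sex = ifelse(rbinom(n, 1, config$sex_prop_m[[group]]) == 1, "M", "F"),
    education = rtrunc_norm(n, config$edu_mean[[group]],
                            config$edu_sd[[group]], lower = 8),
    stringsAsFactors = FALSE)
}

# n x p additive demographic contribution shared by every raw column.
demo_contribution <- function(demo, p, effects) {
  eff <- (demo$age - 65) * effects$age +
    (demo$sex == "M") * effects$sex +
    (demo$education - 16) * effects$education
  matrix(eff, nrow(demo), p)
}

#' Generate a synthetic cohort with known latent structure
#'
#' Simulates baseline visits for three FTD patient groups and a control
#' group. Patients' cognition block X and brain block Y are built as
#' \code{X = T_x U' + demographics + noise} and
#' \code{Y = T_y V' + demographics + noise}, where \code{T_x[,k]} and
#' \code{T_y[,k]} are bivariate normal with correlation \code{rho[k]} and
#' group-shifted means, and U, V are sparse orthonormal saliences.
#' Controls carry demographic effects and noise only.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with \code{cohort} (a \code{\link{cohort}}) and
#'   \code{truth} (a \code{synthetic_truth} holding the planted saliences,
#'   latent scores and realized correlations, for recovery tests).
#' @examples
#' sim <- generate_cohort(sim_config(n_per_group = c(bvFTD = 20, svPPA = 15,
#'   nfvPPA = 15, control = 20), seed = 7))
#' table(sim$cohort$data$group)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config, null_mode = FALSE) {
  K <- config$n_latent
  p_cog <- config$p_cog
  p_brain <- config$p_brain
  U <- sparse_orthonormal(p_cog, K, config$salience_sparsity)
  V <- sparse_orthonormal(p_brain, K, config$salience_sparsity)
  rownames(U) <- cognition_battery(p_cog)
  rownames(V) <- brain_region_names(p_brain)

  groups <- names(config$n_per_group)
  rows <- list(); Tx_all <- NULL; Ty_all <- NULL
  subj_counter <- 0L
  for (g in groups) {
    n <- config$n_per_group[[g]]
    demo <- draw_demographics(n, g, config)
    is_patient <- g != "control"
    if (is_patient && K > 0) {
      shift <- config$group_shift[[g]]
      Tx <- matrix(0, n, K); Ty <- matrix(0, n, K)
      for (k in seq_len(K)) {
        r <- config$rho[k]
        z1 <- rnorm(n); z2 <- rnorm(n)
        Tx[, k] <- shift[k] + z1
        Ty[, k] <- shift[k] + r * z1 + sqrt(1 - r^2) * z2
      }
      Xsig <- Tx %*% t(U); Ysig <- Ty %*% t(V)
    } else {
      Tx <- matrix(0, n, max(K, 0)); Ty <- Tx
      Xsig <- matrix(0, n, p_cog); Ysig <- matrix(0, n, p_brain)
    }
    X <- Xsig + demo_contribution(demo, p_cog, config$demo_effects) +
      matrix(rnorm(n * p_cog, sd = config$noise_sd), n, p_cog)
    Y <- Ysig + demo_contribution(demo, p_brain, config$demo_effects) +
      matrix(rnorm(n * p_brain, sd = config$noise_sd), n, p_brain)
    site <- if (is.null(config$site_labels)) rep(NA_character_, n)
            else sample(config$site_labels, n, replace = TRUE)
    if (!is.null(config$site_labels)) {
      off <- config$site_offsets[match(site, config$site_labels)]
      X <- X + off; Y <- Y + off
    }
    ids <- sprintf("S%04d", subj_counter + seq_len(n))
    subj_counter <- subj_counter + n
    df <- data.frame(subject_id = ids, visit = "baseline",
                     years_since_baseline = 0, group = g, site = site,
                     demo, stringsAsFactors = FALSE)
    colnames(X) <- cognition_battery(p_cog)
    colnames(Y) <- brain_region_names(p_brain)
    rows[[g]] <- cbind(df, X, Y)
    if (is_patient) {
      rownames(Tx) <- ids; rownames(Ty) <- ids
      Tx_all <- rbind(Tx_all, Tx); Ty_all <- rbind(Ty_all, Ty)
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  cohort <- new_cohort(data, cog_cols = cognition_battery(p_cog),
                       brain_cols = brain_region_names(p_brain))
  # realized correlation is pooled within group (group shifts would
  # otherwise inflate the cross-block correlation of the latent scores)
  pg <- setdiff(groups, "control")
  grp <- rep(pg, times = config$n_per_group[pg])
  rho_realized <- if (K > 0 && !null_mode)
    vapply(seq_len(K), function(k) {
      cx <- Tx_all[, k] - stats::ave(Tx_all[, k], grp)
      cy <- Ty_all[, k] - stats::ave(Ty_all[, k], grp)
      stats::cor(cx, cy)
    }, 0)
    else numeric(0)
  truth <- structure(list(
    U_true = U, V_true = V,
    latent_x = Tx_all, latent_y = Ty_all,
    rho_target = config$rho, rho_realized = rho_realized,
    group_assignments = stats::setNames(
      data$group[data$visit == "baseline"],
      data$subject_id[data$visit == "baseline"])),
    class = "synthetic_truth")
  list(cohort = cohort, truth = truth)
}

#' Generate a null cohort (independent blocks)
#'
#' Cognition and brain blocks share no latent scores, so every cross-block
#' correlation is zero in the population; used to calibrate the permutation
#' test. The configuration must have \code{n_latent = 0}; marginals then
#' match \code{\link{generate_cohort}} by construction.
#'
#' @param config A \code{\link{sim_config}} with \code{n_latent = 0}.
#' @return A \code{\link{cohort}}.
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_latent > 0)
    stop("null cohorts require n_latent = 0 (no planted latent structure)")
  with_seed(config$seed, generate_cohort_impl(config, null_mode = TRUE))$cohort
}

#' Add follow-up visits to a synthetic cohort
#'
#' For each selected patient, draws a positive follow-up interval (years),
#' advances both blocks' latent scores by \code{drift_per_group * interval},
#' ages the subject, and regenerates the observed blocks with fresh noise.
#'
#' @param cohort Baseline \code{\link{cohort}} from
#'   \code{\link{generate_cohort}}.
#' @param truth Matching \code{synthetic_truth}.
#' @param config The \code{\link{sim_config}} used at baseline.
#' @param subjects Patient subject ids to follow up (default: all patients).
#' @param seed Seed for the follow-up draws (default \code{config$seed + 1}).
#' @return A \code{\link{cohort}} containing baseline and follow-up rows.
#' @export
generate_followup <- function(cohort, truth, config, subjects = NULL,
                              seed = config$seed + 1L) {
  stopifnot(inherits(cohort, "cohort"), inherits(truth, "synthetic_truth"))
  base <- cohort$data[cohort$data$visit == "baseline", ]
  if (nrow(base) == 0) stop("cohort has no baseline rows")
  patients <- base[base$group != "control", ]
  if (is.null(subjects)) subjects <- patients$subject_id
  if (!all(subjects %in% patients$subject_id))
    stop("unknown patient subject ids: ",
         paste(setdiff(subjects, patients$subject_id), collapse = ", "))
  K <- config$n_latent
  fi <- config$followup_interval_mean_sd
  with_seed(seed, {
    out <- lapply(subjects, function(id) {
      row <- base[base$subject_id == id, ]
      g <- row$group
      interval <- rnorm(1, fi[["mean"]], fi[["sd"]])
      while (interval <= 0) interval <- rnorm(1, fi[["mean"]], fi[["sd"]])
      if (K > 0) {
        drift <- config$drift_per_group[[g]] * interval
        tx <- truth$latent_x[id, ] + drift
        ty <- truth$latent_y[id, ] + drift
        xsig <- as.numeric(truth$U_true %*% tx)
        ysig <- as.numeric(truth$V_true %*% ty)
      } else {
        xsig <- numeric(config$p_cog); ysig <- numeric(config$p_brain)
      }
      demo <- data.frame(age = row$age + interval, sex = row$sex,
                         education = row$education)
      x <- xsig + demo_contribution(demo, config$p_cog, config$demo_effects)[1, ] +
        rnorm(config$p_cog, sd = config$noise_sd)
      y <- ysig + demo_contribution(demo, config$p_brain, config$demo_effects)[1, ] +
        rnorm(config$p_brain, sd = config$noise_sd)
      if (!is.null(config$site_labels) && !is.na(row$site)) {
        off <- config$site_offsets[match(row$site, config$site_labels)]
        x <- x + off; y <- y + off
      }
      fu <- row
      fu$visit <- "followup"
      fu$years_since_baseline <- interval
      fu$age <- demo$age
      fu[cohort$cog_cols] <- as.list(x)
      fu[cohort$brain_cols] <- as.list(y)
      fu
    })
    data <- rbind(cohort$data, do.call(rbind, out))
    rownames(data) <- NULL
    new_cohort(data, cohort$cog_cols, cohort$brain_cols)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Planted cohort truth:", ncol(x$U_true), "LV(s);",
      nrow(x$U_true), "cognition x", nrow(x$V_true), "brain loadings\n")
  if (length(x$rho_realized))
    cat("  realized latent correlations:",
        paste(sprintf("%.3f", x$rho_realized), collapse = ", "), "\n")
  invisible(x)
}
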