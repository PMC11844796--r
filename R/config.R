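#' Simulation configuration for synthetic FTD cohorts
#'
#' Builds and validates the parameter set that defines a synthetic cohort:
#' three patient groups (bvFTD, svPPA, nfvPPA) plus demographically matched
#' controls, a cognition block and an atlas-regional brain (DBM) block that
#' share a planted low-rank cross-block correlation structure, and optional
#' follow-up visits with group-specific yearly drift of the latent scores.
#'
#' Latent scores for each planted latent variable (LV) are bivariate normal
#' across the two blocks with correlation \code{rho[k]}; group mean shifts
#' are applied to both blocks' latent scores. Observed variables are
#' \code{latent \%*\% t(salience) + demographic effects + Gaussian noise}.
#'
#' @param n_per_group Named counts for \code{bvFTD}, \code{svPPA},
#'   \code{nfvPPA}, \code{control}. Defaults mirror the FTLDNI baseline
#'   sample (70/36/30) with 50 controls.
#' @param p_cog Number of cognition columns (default 12).
#' @param p_brain Number of brain (regional DBM) columns (default 102,
#'   the CerebrA atlas parcel count).
#' @param n_latent Number of planted LVs, \code{K_true}.
#' @param rho Length-\code{n_latent} cross-block latent correlations in [0,1].
#' @param salience_sparsity Fraction of exactly-zero loadings per planted
#'   salience vector.
#' @param group_shift Named list (\code{bvFTD}, \code{svPPA}, \code{nfvPPA})
#'   of length-\code{n_latent} mean offsets applied to both blocks' latent
#'   scores. \code{NULL} uses package defaults.
#' @param demo_effects Named list with scalar linear coefficients
#'   \code{age} (per year, centred at 65), \code{sex} (M vs F) and
#'   \code{education} (per year, centred at 16) applied additively to every
#'   raw column of both blocks.
#' @param noise_sd Residual standard deviation of observed variables (> 0).
#' @param site_labels Optional character vector of site names; subjects are
#'   assigned uniformly at random.
#' @param site_offsets Optional numeric vector (one per site) added to all
#'   raw columns of both blocks.
#' @param followup_interval_mean_sd Mean and SD (years) of the baseline to
#'   follow-up interval; defaults 1.03/0.44, the published visit spacing.
#' @param drift_per_group Named list of per-LV yearly latent drift for the
#'   three patient groups. \code{NULL} uses package defaults.
#' @param sex_prop_m Named per-group probability of male sex.
#' @param age_mean,age_sd,edu_mean,edu_sd Named per-group demographic
#'   parameters (years); education is truncated at >= 8 years.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_per_group = c(bvFTD = 70, svPPA = 36, nfvPPA = 30,
                                       control = 50),
                       p_cog = 12, p_brain = 102,
                       n_latent = 4,
                       rho = c(0.7, 0.55, 0.4, 0.3)[seq_len(n_latent)],
                       salience_sparsity = 0.5,
                       group_shift = NULL,
                       demo_effects = list(age = 0.01, sex = 0.1,
                                           education = 0.02),
                       noise_sd = 0.3,
                       site_labels = NULL, site_offsets = NULL,
                       followup_interval_mean_sd = c(mean = 1.03, sd = 0.44),
                       drift_per_group = NULL,
                       sex_prop_m = c(bvFTD = 0.67, svPPA = 0.56,
                                      nfvPPA = 0.47, control = 0.50),
                       age_mean = c(bvFTD = 61.5, svPPA = 63.0,
                                    nfvPPA = 68.1, control = 64.5),
                       age_sd = c(bvFTD = 6.4, svPPA = 6.3,
                                  nfvPPA = 7.9, control = 7.0),
                       edu_mean = c(bvFTD = 15.6, svPPA = 17.0,
                                    nfvPPA = 16.9, control = 17.0),
                       edu_sd = c(bvFTD = 2.9, svPPA = 2.9,
                                  nfvPPA = 3.3, control = 3.0),
                       seed = 1L) {
  groups <- c("bvFTD", "svPPA", "nfvPPA", "control")
  patient_groups <- groups[1:3]

  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (!all(groups %in% names(n_per_group)))
    stop("n_per_group must name all of: ", paste(groups, collapse = ", "))
  if (any(n_per_group < 1))
    stop("invalid config field 'n_per_group': all counts must be >= 1")
  if (p_cog < 1 || p_brain < 1)
    stop("invalid config field 'p_cog'/'p_brain': must be >= 1")
  if (n_latent < 0)
    stop("invalid config field 'n_latent': must be >= 0")
  if (n_latent > 0) {
    if (length(rho) != n_latent)
      stop("invalid config field 'rho': need one entry per planted LV")
    if (any(rho < 0 | rho > 1))
      stop("invalid config field 'rho': entries must lie in [0, 1]")
  } else {
    rho <- numeric(0)
  }
  if (salience_sparsity < 0 || salience_sparsity >= 1)
    stop("invalid config field 'salience_sparsity': must be in [0, 1)")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("invalid config field 'noise_sd': must be > 0")
  if (!is.null(site_labels)) {
    if (is.null(site_offsets) || length(site_offsets) != length(site_labels))
      stop("invalid config field 'site_offsets': one offset per site label")
  }
  fi <- unname(followup_interval_mean_sd)
  if (length(fi) != 2 || fi[1] <= 0 || fi[2] < 0)
    stop("invalid config field 'followup_interval_mean_sd'")

  if (is.null(group_shift)) {
    base <- list(bvFTD  = c(-0.6,  0.9,  0.3, -0.4),
                 svPPA  = c( 1.3, -0.2, -0.5,  0.3),
                 nfvPPA = c(-0.7, -1.0,  0.6,  0.5))
    group_shift <- lapply(base, function(v) rep_len(v, max(n_latent, 1))[seq_len(n_latent)])
  }
  if (n_latent > 0 &&
      (!all(patient_groups %in% names(group_shift)) ||
       any(vapply(group_shift[patient_groups], length, 1L) != n_latent)))
    stop("invalid config field 'group_shift': need length-", n_latent,
         " offsets for bvFTD, svPPA, nfvPPA")

  if (is.null(drift_per_group)) {
    base <- list(bvFTD  = c(0.25, 0.20, 0.10, 0.05),
                 svPPA  = c(0.60, 0.25, 0.10, 0.05),
                 nfvPPA = c(0.20, 0.15, 0.10, 0.05))
    drift_per_group <- lapply(base, function(v) rep_len(v, max(n_latent, 1))[seq_len(n_latent)])
  }

  for (f in c("sex_prop_m", "age_mean", "age_sd", "edu_mean", "edu_sd")) {
    v <- get(f)
    if (!all(groups %in% names(v)))
      stop("invalid config field '", f, "': must be named per group")
  }

  structure(list(
    n_per_group = n_per_group[groups], p_cog = p_cog, p_brain = p_brain,
    n_latent = n_latent, rho = rho, salience_sparsity = salience_sparsity,
    group_shift = group_shift, demo_effects = demo_effects,
    noise_sd = noise_sd, site_labels = site_labels,
    site_offsets = site_offsets,
    followup_interval_mean_sd = c(mean = fi[1], sd = fi[2]),
    drift_per_group = drift_per_group, sex_prop_m = sex_prop_m,
    age_mean = age_mean, age_sd = age_sd,
    edu_mean = edu_mean, edu_sd = edu_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic FTD cohort configuration\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$n_per_group),
                                 x$n_per_group), collapse = ", "), "\n")
  cat("  blocks: ", x$p_cog, " cognition x ", x$p_brain, " brain columns\n",
      sep = "")
  cat("  planted LVs:", x$n_latent,
      if (x$n_latent) paste0("(rho = ",
                             paste(format(x$rho), collapse = ", "), ")"), "\n")
  cat("  noise SD:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}

# Default cognition column names: the clinical battery of an FTD study
# (CDR subscales, MMSE, naming, verbal learning, span, fluency ...).
# Names carry no semantics beyond making reports readable; the CDR and BNT
# columns are the ones picked up by the "minimal" classifier feature set.
cognition_battery <- function(p_cog) {
  battery <- c("cdr_sumboxes", "cdr_language", "cdr_behaviour", "mmse",
               "bnt", "ppvt", "cvlt_memory", "cvlt_recall_30s",
               "cvlt_recall_10min", "digit_span_forward",
               "digit_span_backward", "fluency_semantic",
               "fluency_phonological", "mtmt_correct_lines", "mtmt_time",
               "cvlt_recognition")
  if (p_cog <= length(battery)) battery[seq_len(p_cog)]
  else c(battery, sprintf("cog_%02d", seq_len(p_cog - length(battery))))
}

brain_region_names <- function(p_brain) sprintf("cerebra_%03d", seq_len(p_brain))

# Run `code` under a given RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
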