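# Shared fixtures: small cohort configurations and convenience wrappers
# used across the unit and acceptance suites.

# Small 3-group cohort (fast) with planted 2-LV structure.
small_config <- function(seed = 1, ...) {
  args <- list(
    n_per_group = c(bvFTD = 30, svPPA = 25, nfvPPA = 25, control = 25),
    p_cog = 10, p_brain = 30, n_latent = 2, rho = c(0.7, 0.5),
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Config with no demographic confounds: blocks of a null cohort are then
# strictly independent.
clean_null_config <- function(seed, n = 100, p_cog = 12, p_brain = 102) {
  sim_config(n_per_group = c(bvFTD = ceiling(n / 2), svPPA = floor(n / 4),
                             nfvPPA = n - ceiling(n / 2) - floor(n / 4),
                             control = 1),
             p_cog = p_cog, p_brain = p_brain, n_latent = 0,
             demo_effects = list(age = 0, sex = 0, education = 0),
             seed = seed)
}

# Z-scored patient blocks of a cohort.
patient_blocks <- function(cohort) {
  X <- cohort_block(cohort, "cognition", visit = "baseline",
                    groups = "patients")
  Y <- cohort_block(cohort, "brain", visit = "baseline",
                    groups = "patients")
  list(X = X, Y = Y,
       Xz = zscore_columns(X)$block, Yz = zscore_columns(Y)$block)
}

# Wide-margin separable 3-class features: class means far apart relative
# to unit noise, so any discriminant classifier approaches 100%.
separable_classes <- function(n_per_class = 40, gap = 8, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    centers <- rbind(c(0, 0), c(gap, 0), c(0, gap))
    x <- do.call(rbind, lapply(1:3, function(c)
      cbind(rnorm(n_per_class, centers[c, 1]),
            rnorm(n_per_class, centers[c, 2]))))
    colnames(x) <- c("f1", "f2")
    list(x = x, y = factor(rep(c("a", "b", "c"), each = n_per_class)))
  })
}
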