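# Cohort I/O and preprocessing: round-trips, imputation, complete-case
# filtering, z-scores, control-referenced w-scores.

make_toy_cohort <- function(n = 10, seed = 1) {
  set.seed(seed)
  cogs <- c("mmse", "bnt"); brains <- c("cerebra_001", "cerebra_002")
  d <- data.frame(
    subject_id = sprintf("S%02d", 1:n), visit = "baseline",
    years_since_baseline = 0,
    group = rep(c("bvFTD", "svPPA", "nfvPPA"), length.out = n),
    site = NA_character_,
    age = round(rnorm(n, 65, 5), 3),
    sex = sample(c("M", "F"), n, replace = TRUE),
    education = round(rnorm(n, 16, 2), 3),
    mmse = round(rnorm(n, 24, 4), 6), bnt = round(rnorm(n, 10, 3), 6),
    cerebra_001 = rnorm(n), cerebra_002 = rnorm(n))
  new_cohort(d, cogs, brains)
}

test_that("write then read round-trips losslessly in both dialects", {
  coh <- make_toy_cohort()
  schema <- list(cog_cols = coh$cog_cols, brain_cols = coh$brain_cols)
  for (ext in c("csv", "tsv")) {
    path <- file.path(tempdir(), paste0("cohort.", ext))
    write_cohort(coh, path)
    back <- read_cohort(path, schema)
    expect_equal(back$data[coh$cog_cols], coh$data[coh$cog_cols],
                 tolerance = 1e-15)
    expect_identical(back$data$subject_id, coh$data$subject_id)
  }
  # identical content parsed from both dialects is identical
  a <- read_cohort(file.path(tempdir(), "cohort.csv"), schema)
  b <- read_cohort(file.path(tempdir(), "cohort.tsv"), schema)
  expect_equal(a$data, b$data)
})

test_that("schema violations are rejected with named offenders", {
  coh <- make_toy_cohort()
  d <- coh$data
  d2 <- rbind(d, d[1, ])
  expect_error(new_cohort(d2, coh$cog_cols, coh$brain_cols),
               "S01 baseline")
  d3 <- d; d3$mmse <- as.character(d3$mmse); d3$mmse[2] <- "abc"
  expect_error(new_cohort(d3, coh$cog_cols, coh$brain_cols), "mmse")
  expect_error(new_cohort(d[, -1], coh$cog_cols, coh$brain_cols),
               "subject_id")
  d4 <- d; d4$visit[2] <- "followup"   # followup without baseline row
  expect_error(new_cohort(d4, coh$cog_cols, coh$brain_cols),
               "without baseline")
  d5 <- rbind(d, d[2, ])               # followup with zero interval
  d5$visit[nrow(d5)] <- "followup"
  expect_error(new_cohort(d5, coh$cog_cols, coh$brain_cols),
               "years_since_baseline")
  expect_error(read_cohort(file.path(tempdir(), "no-such-file.csv"),
                           list(cog_cols = "a", brain_cols = "b")),
               "not found")
})

test_that("group-mean imputation fills by diagnostic group only", {
  coh <- make_toy_cohort(n = 9)
  coh$data$education <- c(14, 10, 20, 16, 12, 22, NA, NA, NA)
  # groups cycle bvFTD, svPPA, nfvPPA; rows 7..9 are one missing per group
  out <- impute_group_mean(coh, "education")
  expect_equal(out$data$education[7:9], c(15, 11, 21))
  # forced arithmetic: {14, 16, NA} -> 15
  coh2 <- make_toy_cohort(n = 6)
  coh2$data$group <- "bvFTD"
  coh2$data$education <- c(14, 16, NA, 13, 15, 17)
  expect_equal(impute_group_mean(coh2, "education")$data$education[3], 15)
  # observed cells untouched; group means preserved
  expect_equal(out$data$education[1:6], coh$data$education[1:6])
  for (g in unique(out$data$group))
    expect_equal(mean(out$data$education[out$data$group == g]),
                 mean(coh$data$education[coh$data$group == g], na.rm = TRUE))
  # no missing -> unchanged; all-missing group -> error
  expect_identical(impute_group_mean(out, "education")$data, out$data)
  coh3 <- make_toy_cohort(n = 6)
  coh3$data$education[coh3$data$group == "svPPA"] <- NA
  expect_error(impute_group_mean(coh3, "education"), "svPPA")
})

test_that("complete-case filtering equals a brute-force row scan", {
  set.seed(7)
  coh <- make_toy_cohort(n = 30)
  req <- c("mmse", "bnt", "education")
  mask <- matrix(runif(30 * 3) < 0.15, 30, 3)
  for (j in 1:3) coh$data[[req[j]]][mask[, j]] <- NA
  out <- complete_case_filter(coh, req)
  keep_brute <- !apply(is.na(coh$data[req]), 1, any)
  expect_identical(out$cohort$data$subject_id,
                   coh$data$subject_id[keep_brute])
  expect_equal(out$exclusions$n_removed, sum(!keep_brute))
  expect_equal(unname(out$exclusions$by_column),
               unname(colSums(is.na(coh$data[req]))))
  # identity when nothing is missing
  clean <- make_toy_cohort(n = 5)
  expect_identical(complete_case_filter(clean, req)$cohort$data, clean$data)
  # everything missing -> error
  allna <- make_toy_cohort(n = 4)
  allna$data$mmse <- NA_real_
  expect_error(complete_case_filter(allna, "mmse"), "every row")
})

test_that("z-scoring matches hand computation and inverts exactly", {
  B <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  z <- zscore_columns(B)
  expect_equal(z$block[, "a"], (c(1, 2, 3) - 2) / 1, ignore_attr = TRUE)
  expect_equal(z$block[, "b"], (c(10, 20, 60) - 30) / sd(c(10, 20, 60)),
               ignore_attr = TRUE)
  expect_equal(colMeans(z$block), c(a = 0, b = 0))
  expect_equal(apply(z$block, 2, sd), c(a = 1, b = 1))
  # inverse transform recovers input
  back <- sweep(sweep(z$block, 2, z$stats$sd, "*"), 2, z$stats$mean, "+")
  expect_equal(back, B, tolerance = 1e-10)
  # baseline-referenced mode: identical rows give identical z-scores
  z2 <- zscore_columns(B, z$stats)
  expect_equal(z2$block, z$block)
  expect_error(zscore_columns(cbind(B, c = c(5, 5, 5))), "c")
})

test_that("w-scores are calibrated on control-like patients", {
  set.seed(21)
  gen <- function(n) {
    age <- rnorm(n, 65, 7); sex <- sample(c("M", "F"), n, TRUE)
    edu <- rnorm(n, 16, 3)
    data.frame(age, sex, education = edu,
               v1 = 0.05 * (age - 65) + 0.4 * (sex == "M") + rnorm(n),
               v2 = -0.03 * (edu - 16) + rnorm(n))
  }
  controls <- gen(300)
  patients <- gen(500)          # same generative model as controls
  W <- wscore_adjust(patients, controls, c("v1", "v2"))
  expect_lt(max(abs(colMeans(W))), 0.1)
  expect_true(all(apply(W, 2, sd) > 0.9 & apply(W, 2, sd) < 1.1))
})

test_that("w-score of prediction + 2 residual SDs is exactly 2", {
  set.seed(3)
  controls <- data.frame(age = rnorm(40, 65, 5),
                         sex = sample(c("M", "F"), 40, TRUE),
                         education = rnorm(40, 16, 2))
  controls$v <- 1 + 0.1 * controls$age + rnorm(40)
  X <- cbind(1, controls$age, as.numeric(controls$sex == "M"),
             controls$education)
  fit <- lm.fit(X, controls$v)
  sigma <- sqrt(sum(fit$residuals^2) / (40 - 3 - 1))
  pat <- data.frame(age = 70, sex = "F", education = 12)
  pat$v <- sum(c(1, 70, 0, 12) * fit$coefficients) + 2 * sigma
  expect_equal(unname(wscore_adjust(pat, controls, "v")[1, 1]), 2,
               tolerance = 1e-10)
  # constant control variable -> zero residual SD -> error
  controls$const <- 5
  expect_error(wscore_adjust(pat, controls, "const"), "zero")
})

test_that("w-scores are invariant to affine rescaling of a covariate", {
  set.seed(9)
  controls <- data.frame(age = rnorm(60, 65, 6),
                         sex = sample(c("M", "F"), 60, TRUE),
                         education = rnorm(60, 16, 3))
  controls$v <- 0.08 * controls$age + rnorm(60)
  patients <- controls[1:20, ]
  w_years <- wscore_adjust(patients, controls, "v")
  controls$age <- controls$age * 12 + 7   # months, shifted
  patients$age <- patients$age * 12 + 7
  w_months <- wscore_adjust(patients, controls, "v")
  expect_equal(w_years, w_months, tolerance = 1e-8)
})
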