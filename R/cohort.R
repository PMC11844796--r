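# Cohort container + file I/O + preprocessing (imputation, complete-case
# filtering, z-scoring, control-referenced w-scores).

META_COLS <- c("subject_id", "visit", "years_since_baseline", "group",
               "site", "age", "sex", "education")

#' Cohort table of subject-visit rows
#'
#' A light S3 wrapper around a data.frame of subject-visit rows with
#' declared cognition and brain column sets. Mandatory metadata columns:
#' subject_id, visit (baseline/followup), years_since_baseline, group
#' (bvFTD/svPPA/nfvPPA/control), site (may be NA), age, sex (M/F),
#' education.
#'
#' @param data data.frame holding metadata plus numeric block columns.
#' @param cog_cols Character vector of cognition column names.
#' @param brain_cols Character vector of brain column names.
#' @return An object of class \code{"cohort"}.
#' @export
new_cohort <- function(data, cog_cols, brain_cols) {
  missing_meta <- setdiff(META_COLS, names(data))
  if (length(missing_meta))
    stop("cohort schema error: missing mandatory columns: ",
         paste(missing_meta, collapse = ", "))
  missing_blocks <- setdiff(c(cog_cols, brain_cols), names(data))
  if (length(missing_blocks))
    stop("cohort schema error: declared block columns absent: ",
         paste(missing_blocks, collapse = ", "))
  key <- paste(data$subject_id, data$visit)
  if (anyDuplicated(key))
    stop("cohort schema error: duplicated (subject, visit): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  fu <- data$subject_id[data$visit == "followup"]
  orphan <- setdiff(fu, data$subject_id[data$visit == "baseline"])
  if (length(orphan))
    stop("cohort schema error: follow-up rows without baseline: ",
         paste(orphan, collapse = ", "))
  bad_time <- (data$visit == "baseline") != (data$years_since_baseline == 0)
  if (any(bad_time, na.rm = TRUE))
    stop("cohort schema error: years_since_baseline must be 0 iff baseline")
  for (cl in c(cog_cols, brain_cols)) {
    if (!is.numeric(data[[cl]]))
      stop("cohort schema error: non-numeric cells in column ", cl)
  }
  structure(list(data = data, cog_cols = cog_cols, brain_cols = brain_cols),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$data), "subject-visit rows (",
      sum(x$data$visit == "baseline"), "baseline /",
      sum(x$data$visit == "followup"), "follow-up )\n")
  print(table(group = x$data$group, visit = x$data$visit))
  cat("Blocks:", length(x$cog_cols), "cognition,",
      length(x$brain_cols), "brain columns\n")
  invisible(x)
}

#' Extract a numeric block from a cohort
#'
#' @param cohort A \code{\link{cohort}}.
#' @param block One of \code{"cognition"}, \code{"brain"}.
#' @param visit Optional visit filter (\code{"baseline"}, \code{"followup"}).
#' @param groups Optional group filter; \code{"patients"} selects the three
#'   FTD groups.
#' @return Numeric matrix with subject ids as rownames.
#' @export
cohort_block <- function(cohort, block = c("cognition", "brain"),
                         visit = NULL, groups = NULL) {
  block <- match.arg(block)
  cols <- if (block == "cognition") cohort$cog_cols else cohort$brain_cols
  d <- cohort$data
  if (!is.null(visit)) d <- d[d$visit %in% visit, ]
  if (!is.null(groups)) {
    if (identical(groups, "patients")) groups <- c("bvFTD", "svPPA", "nfvPPA")
    d <- d[d$group %in% groups, ]
  }
  m <- as.matrix(d[cols])
  rownames(m) <- d$subject_id
  m
}

#' Read / write a cohort table
#'
#' CSV or TSV (by file extension), UTF-8, missing values as empty cell or
#' \code{NA}. The schema declares which columns are cognition and brain;
#' round-trip write-then-read is lossless to 15 significant digits.
#'
#' @param path File path ending in \code{.csv} or \code{.tsv}.
#' @param schema List with \code{cog_cols} and \code{brain_cols}.
#' @return \code{read_cohort}: a \code{\link{cohort}};
#'   \code{write_cohort}: the path, invisibly.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, na.strings = c("", "NA"),
                            check.names = FALSE, fileEncoding = "UTF-8")
  for (cl in intersect(c(schema$cog_cols, schema$brain_cols,
                         "age", "education", "years_since_baseline"),
                       names(data))) {
    if (!is.numeric(data[[cl]])) {
      bad <- !is.na(data[[cl]]) & is.na(suppressWarnings(as.numeric(data[[cl]])))
      if (any(bad))
        stop("cohort schema error: non-numeric cells in column ", cl,
             " (rows ", paste(which(bad), collapse = ", "), ")")
      data[[cl]] <- as.numeric(data[[cl]])
    }
  }
  if (!"site" %in% names(data)) data$site <- NA_character_
  new_cohort(data, schema$cog_cols, schema$brain_cols)
}

#' @rdname read_cohort
#' @param cohort A \code{\link{cohort}} to write.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- cohort$data
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) format(x, digits = 17, trim = TRUE,
                                              scientific = FALSE))
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Impute missing values by diagnostic-group mean
#'
#' Replaces missing cells in the named columns by the mean of observed
#' values within the row's diagnostic group; observed cells are untouched.
#' By default only \code{education} is imputed.
#'
#' @param cohort A \code{\link{cohort}}.
#' @param columns Columns to impute (default \code{"education"}).
#' @return The imputed \code{\link{cohort}}.
#' @export
impute_group_mean <- function(cohort, columns = "education") {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  for (cl in columns) {
    if (!cl %in% names(d)) stop("unknown column: ", cl)
    for (g in unique(d$group)) {
      idx <- d$group == g
      obs <- d[[cl]][idx & !is.na(d[[cl]])]
      miss <- idx & is.na(d[[cl]])
      if (any(miss)) {
        if (length(obs) == 0)
          stop("cannot impute column ", cl, ": group ", g,
               " has no observed values")
        d[[cl]][miss] <- mean(obs)
      }
    }
  }
  cohort$data <- d
  cohort
}

#' Complete-case filtering
#'
#' Removes subject-visit rows missing any required value and reports the
#' exclusions per group and per column.
#'
#' @param cohort A \code{\link{cohort}}.
#' @param required_columns Columns that must be observed.
#' @return List with the filtered \code{cohort} and an \code{exclusions}
#'   report (\code{n_removed}, per-group and per-column counts).
#' @export
complete_case_filter <- function(cohort, required_columns) {
  stopifnot(inherits(cohort, "cohort"))
  absent <- setdiff(required_columns, names(cohort$data))
  if (length(absent)) stop("unknown required columns: ",
                           paste(absent, collapse = ", "))
  d <- cohort$data
  miss <- is.na(as.matrix(d[required_columns]))
  drop <- rowSums(miss) > 0
  if (all(drop))
    stop("complete-case filter removed every row; relax required_columns")
  report <- list(
    n_removed = sum(drop),
    by_group = if (any(drop)) table(d$group[drop]) else table(character(0)),
    by_column = colSums(miss))
  # dropping a baseline row orphans its follow-up; drop those too
  keep <- d[!drop, ]
  orphan <- keep$visit == "followup" &
    !keep$subject_id %in% keep$subject_id[keep$visit == "baseline"]
  report$n_orphaned_followups <- sum(orphan)
  cohort$data <- keep[!orphan, ]
  list(cohort = cohort, exclusions = report)
}

#' Column standardization (z-scores)
#'
#' Standardizes each column to (x - mean) / SD with the unbiased SD
#' (divisor n - 1). In self mode the block's own statistics are used and
#' returned; supplying \code{stats} (e.g. baseline statistics applied to
#' follow-up rows) standardizes against that reference instead.
#'
#' @param block Numeric matrix (columns named).
#' @param stats Optional \code{standardization_stats} from a previous call.
#' @return List with \code{block} (standardized matrix) and \code{stats}.
#' @export
zscore_columns <- function(block, stats = NULL) {
  block <- as.matrix(block)
  if (is.null(stats)) {
    mu <- colMeans(block)
    sd <- apply(block, 2, stats::sd)
    zero <- sd <= 0 | !is.finite(sd)
    if (any(zero))
      stop("zero-SD column(s) in self mode: ",
           paste(colnames(block)[zero], collapse = ", "))
    stats <- structure(list(mean = mu, sd = sd, reference = "self"),
                       class = "standardization_stats")
  } else {
    if (!all(colnames(block) %in% names(stats$mean)))
      stop("standardization stats do not cover columns: ",
           paste(setdiff(colnames(block), names(stats$mean)), collapse = ", "))
    stats$mean <- stats$mean[colnames(block)]
    stats$sd <- stats$sd[colnames(block)]
  }
  z <- sweep(sweep(block, 2, stats$mean), 2, stats$sd, "/")
  list(block = z, stats = stats)
}

#' Control-referenced w-scores
#'
#' For each variable, fits ordinary least squares on the control group with
#' intercept + covariates (age, sex, education by default), then expresses
#' each patient value as (observed - predicted) / SD(control residuals),
#' the residual standard error with divisor (n - p - 1). The result is a
#' demographically adjusted z-score relative to healthy controls.
#'
#' @param patients Patient data.frame or cohort rows containing
#'   \code{variables} and \code{covariates}.
#' @param controls Control data.frame, complete-case on
#'   \code{variables} + \code{covariates}.
#' @param variables Character vector of columns to adjust.
#' @param covariates Covariate columns (default age, sex, education). Sex
#'   is encoded 0/1 (F/M).
#' @return Matrix of patient w-scores (rows as in \code{patients}).
#' @export
wscore_adjust <- function(patients, controls, variables,
                          covariates = c("age", "sex", "education")) {
  enc <- function(d) {
    m <- matrix(1, nrow(d), 1)
    for (cv in covariates) {
      v <- d[[cv]]
      if (cv == "sex" || is.character(v) || is.factor(v))
        v <- as.numeric(as.character(v) == "M")
      m <- cbind(m, v)
    }
    colnames(m) <- c("(Intercept)", covariates)
    m
  }
  Xc <- enc(controls)
  if (anyNA(Xc) || anyNA(as.matrix(controls[variables])))
    stop("controls must be complete-case on variables and covariates")
  n <- nrow(Xc); p <- length(covariates)
  if (n < p + 2)
    stop("need at least ", p + 2, " controls for ", p, " covariates")
  if (qr(Xc)$rank < ncol(Xc))
    stop("rank-deficient covariate design in controls")
  Xp <- enc(patients)
  W <- matrix(NA_real_, nrow(patients), length(variables),
              dimnames = list(rownames(patients), variables))
  for (v in variables) {
    fit <- stats::lm.fit(Xc, controls[[v]])
    sigma <- sqrt(sum(fit$residuals^2) / (n - p - 1))
    if (!is.finite(sigma) || sigma <= 0)
      stop("control residual SD is zero for variable ", v)
    pred <- as.numeric(Xp %*% fit$coefficients)
    W[, v] <- (patients[[v]] - pred) / sigma
  }
  W
}
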