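# Cohort-level statistics: reference Z-scores, ANOVA + Tukey + BH-FDR,
# Spearman correlation, standardized multivariable OLS.

#' Z-scores against a reference subgroup
#'
#' Normalizes a biomarker by the mean and standard deviation of a
#' reference subset (the young cognitively unimpaired group in the default
#' pipeline). Inputs should already be ICV-residualized where applicable.
#'
#' @param values numeric vector.
#' @param is_reference logical vector marking the reference members.
#' @return Numeric vector of Z-scores.
#' @export
zscores_vs_reference <- function(values, is_reference) {
  stopifnot(length(values) == length(is_reference))
  ref <- values[is_reference]
  if (length(ref) < 2L) stop("need >= 2 reference members")
  s <- stats::sd(ref)
  if (s == 0) stop("degenerate reference: zero spread")
  (values - mean(ref)) / s
}

#' One-way ANOVA with Tukey HSD and BH-FDR corrected pairwise tests
#'
#' Classical one-way F-test followed by Tukey honestly-significant-
#' difference pairwise comparisons (studentized-range p-values), with
#' Benjamini-Hochberg step-up correction applied across the pairwise
#' family at level `q`. Groups with fewer than 2 members are dropped with
#' a warning; small groups (n < 5, e.g. a rare biomarker stage) trigger a
#' low-n warning but are kept.
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor).
#' @param q FDR level for the pairwise family (default 0.05).
#' @return A `group_comparison` object: `f_stat`, `df`, `p`, and a
#'   `pairwise` data frame (groupA, groupB, mean_diff, tukey_p,
#'   fdr_adjusted_p, reject).
#' @export
oneway_anova_tukey <- function(values, groups, q = 0.05) {
  groups <- factor(groups)
  tab <- table(groups)
  if (any(tab < 2L)) {
    warning("dropping group(s) with n < 2: ",
            paste(names(tab)[tab < 2L], collapse = ", "))
    keep <- groups %in% names(tab)[tab >= 2L]
    values <- values[keep]; groups <- droplevels(groups[keep])
    tab <- table(groups)
  }
  if (nlevels(groups) < 2L) stop("need >= 2 groups with >= 2 members")
  if (stats::sd(values) == 0) stop("undefined F: all values identical")
  if (any(tab < 5L))
    warning("low-n group(s) (n < 5) retained in pairwise tests: ",
            paste(names(tab)[tab < 5L], collapse = ", "))
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  adj <- stats::p.adjust(tk[, "p adj"], method = "BH")
  pairwise <- data.frame(
    groupA = vapply(pair_names, `[`, "", 1L),
    groupB = vapply(pair_names, `[`, "", 2L),
    mean_diff = tk[, "diff"],
    tukey_p = tk[, "p adj"],
    fdr_adjusted_p = adj,
    reject = adj <= q,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(f_stat = an[["F value"]][1],
                 df = c(between = an[["Df"]][1], within = an[["Df"]][2]),
                 p = an[["Pr(>F)"]][1],
                 pairwise = pairwise, q = q),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$df[1], x$df[2], x$f_stat, x$p))
  cat(sprintf("Tukey HSD pairwise tests, BH-FDR at q = %.2f:\n", x$q))
  print(format(x$pairwise, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (BH-adjusted p-values) and `reject`
#'   (logical flags, `adjusted <= q`).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1 | !is.finite(pvalues)))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Spearman rank correlation with large-sample p-value
#'
#' Rank correlation with average ranks for ties; the p-value comes from
#' the large-sample t approximation t = rho * sqrt((n-2)/(1-rho^2)) on
#' n - 2 degrees of freedom (two-sided).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n < 4L || length(y) != n) stop("need equal-length vectors, n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) p <- 0
  else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

#' Standardized multivariable linear regression
#'
#' Fits an OLS model of a standardized outcome on standardized predictors
#' plus covariates. Continuous variables are scaled to mean 0, SD 1;
#' binary (0/1) variables are centred but not variance-scaled, so their
#' coefficients remain per-category effects. Covariates are always
#' included in the fit but reported separately from the predictors of
#' interest.
#'
#' @param data data frame holding all variables.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param covariates character vector of covariate column names
#'   (default none).
#' @return A `std_ols` object: `beta_std`, `ci95`, `p` (maps over
#'   predictors and covariates), `r2`, `n`, plus the fitted `lm` object.
#' @export
ols_standardized <- function(data, outcome, predictors, covariates = character()) {
  vars <- c(outcome, predictors, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + length(covariates) + 3L)
    stop("too few observations for the number of parameters")
  std <- as.data.frame(lapply(d, standardize_column))
  X <- as.matrix(std[, c(predictors, covariates), drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    bad <- setdiff(colnames(X), colnames(X)[keep - 1L])
    stop("collinear design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  fml <- stats::reformulate(c(predictors, covariates), response = outcome)
  fit <- stats::lm(fml, data = std)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  terms <- c(predictors, covariates)
  structure(list(
    beta_std = stats::coef(fit)[terms],
    ci95 = ci[terms, , drop = FALSE],
    p = sm$coefficients[terms, "Pr(>|t|)"],
    r2 = sm$r.squared,
    n = n,
    predictors = predictors, covariates = covariates,
    fit = fit), class = "std_ols")
}

standardize_column <- function(x) {
  ux <- unique(x)
  if (length(ux) <= 2L && all(ux %in% c(0, 1))) x - mean(x)   # binary: centre only
  else (x - mean(x)) / stats::sd(x)
}

#' @export
print.std_ols <- function(x, ...) {
  cat(sprintf("Standardized OLS (n = %d, R^2 = %.3f)\n", x$n, x$r2))
  tab <- data.frame(beta_std = x$beta_std,
                    ci_lo = x$ci95[, 1], ci_hi = x$ci95[, 2], p = x$p)
  tab$role <- ifelse(rownames(tab) %in% x$covariates, "covariate", "predictor")
  print(format(tab, digits = 3))
  invisible(x)
}

#' @export
coef.std_ols <- function(object, ...) object$beta_std

#' Covariate profiles used by the regression analyses
#'
#' `cov1` = age, sex, APOE4; `cov2` adds ICV; `cov3` adds grey-matter
#' volume (requires a `gm_volume` column).
#'
#' @param profile one of "cov1", "cov2", "cov3", "none".
#' @return Character vector of covariate column names.
#' @export
covariate_profile <- function(profile = c("cov2", "cov1", "cov3", "none")) {
  profile <- match.arg(profile)
  switch(profile,
         none = character(),
         cov1 = c("age", "sex", "apoe4"),
         cov2 = c("age", "sex", "apoe4", "icv"),
         cov3 = c("age", "sex", "apoe4", "icv", "gm_volume"))
}
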