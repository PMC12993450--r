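# Mass-univariate voxel-wise GLM with random-field-theory correction -----

#' Build a voxel-wise design matrix
#'
#' Intercept plus predictor(s) of interest plus covariates, with a
#' contrast vector selecting the tested effect (default: the first
#' predictor).
#'
#' @param cohort data frame of per-participant values.
#' @param predictors character vector of predictor column names.
#' @param covariates character vector of covariate column names.
#' @param contrast optional numeric contrast over the design columns
#'   (intercept first); default tests the first predictor.
#' @return A `design_matrix` object with `X` and `contrast`.
#' @export
design_matrix <- function(cohort, predictors, covariates = character(),
                          contrast = NULL) {
  cols <- c(predictors, covariates)
  X <- cbind(intercept = 1,
             as.matrix(cohort[, cols, drop = FALSE]))
  if (qr(X)$rank < ncol(X))
    stop("collinearity error: design matrix is rank deficient")
  if (is.null(contrast)) {
    contrast <- numeric(ncol(X))
    contrast[2L] <- 1
  }
  if (length(contrast) != ncol(X))
    stop("contrast length must equal the number of design columns")
  structure(list(X = X, contrast = as.numeric(contrast),
                 columns = colnames(X)), class = "design_matrix")
}

#' Voxel-wise linear regression t-map
#'
#' Fits, at every in-mask voxel, an OLS model of the participant volumes
#' on the design matrix, and returns the t-statistic of the contrast.
#' Voxels with zero residual variance get t = 0 when the contrast effect
#' is also zero, and are capped at `t_cap` when the fit is exact with a
#' non-zero effect; both are flagged.
#'
#' @param volumes list of `scalar_volume`s (one per participant, common
#'   grid, same order as the design rows).
#' @param design a [design_matrix()].
#' @param mask logical 3D array of voxels to fit.
#' @param t_cap cap for degenerate (zero-residual) t-values (default 1e6).
#' @param keep_residuals retain residual images for smoothness estimation
#'   (default `TRUE`).
#' @return A `tmap_result` with `tmap` (`scalar_volume`), `df`,
#'   `n_degenerate`, and (if kept) a residual matrix; threshold fields are
#'   unset until [rft_threshold()] is applied.
#' @export
fit_voxelwise <- function(volumes, design, mask, t_cap = 1e6,
                          keep_residuals = TRUE) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (length(volumes) != n) stop("number of volumes must match design rows")
  if (n < p + 3L) stop("need at least rank + 3 participants")
  if (!any(mask)) stop("empty mask")
  dims <- dim(volumes[[1]]$data)
  vx <- volumes[[1]]$voxel_size_mm
  for (v in volumes)
    if (!identical(dim(v$data), dims)) stop("grid mismatch across volumes")

  idx <- which(mask)
  Y <- vapply(volumes, function(v) v$data[idx], numeric(length(idx)))
  Y <- t(Y)                                   # n x V

  qrX <- qr(X)
  if (qrX$rank < p) stop("collinearity error: design matrix is rank deficient")
  beta <- qr.coef(qrX, Y)                     # p x V
  res <- Y - X %*% beta
  df <- n - p
  rss <- colSums(res^2)
  XtXinv <- chol2inv(qr.R(qrX))
  cvar <- drop(t(design$contrast) %*% XtXinv %*% design$contrast)
  eff <- drop(crossprod(design$contrast, beta))
  # degenerate voxels: residual variance indistinguishable from zero
  # relative to the outcome's spread (constant or exactly-fit outcomes)
  varY <- pmax(colSums(Y^2) - n * colMeans(Y)^2, 0)
  degen <- rss <= 1e-12 * (varY + .Machine$double.eps)
  se <- sqrt(pmax(rss, 0) / df * cvar)
  tvals <- eff / se
  tvals[degen & varY <= 1e-12 * n] <- 0           # constant outcome
  exact <- degen & varY > 1e-12 * n               # exact fit, t diverges
  tvals[exact] <- sign(eff[exact]) * t_cap
  tvals[!degen & se == 0] <- 0
  n_degen <- sum(degen | se == 0)

  tarr <- array(0, dims)
  tarr[idx] <- tvals
  structure(list(tmap = scalar_volume(tarr, vx),
                 df = df, mask = mask,
                 n_degenerate = n_degen,
                 residuals = if (keep_residuals) res else NULL,
                 fwhm_est_mm = NULL, resels = NULL,
                 corrected_threshold = NULL, significant_mask = NULL,
                 alpha = NULL),
            class = "tmap_result")
}

#' Estimate smoothness (FWHM) of residual images
#'
#' Standard roughness estimator: residual vectors are normalized to unit
#' norm per voxel, spatial partial derivatives are taken along each axis,
#' and the per-axis FWHM is sqrt(4 log 2 / lambda) with lambda the mean
#' squared derivative per mm.
#'
#' @param residuals n x V residual matrix (as stored by
#'   [fit_voxelwise()]) or a list of residual `scalar_volume`s.
#' @param mask logical 3D array matching the fit.
#' @param voxel_size_mm voxel sizes (needed when `residuals` is a matrix).
#' @return Numeric length-3 vector of per-axis FWHM estimates in mm.
#' @export
estimate_fwhm <- function(residuals, mask, voxel_size_mm = c(2, 2, 2)) {
  if (is.list(residuals) && inherits(residuals[[1]], "scalar_volume")) {
    voxel_size_mm <- residuals[[1]]$voxel_size_mm
    idx <- which(mask)
    residuals <- t(vapply(residuals, function(v) v$data[idx],
                          numeric(length(idx))))
  }
  n <- nrow(residuals)
  if (is.null(n) || n < 3L) stop("need >= 3 residual volumes")
  dims <- dim(mask)
  idx <- which(mask)
  # unit-normalize the residual vector at each voxel
  norms <- sqrt(colSums(residuals^2))
  ok <- norms > 0
  U <- residuals
  U[, ok] <- sweep(residuals[, ok, drop = FALSE], 2, norms[ok], "/")

  arr_idx <- arrayInd(idx, dims)
  voxpos <- array(NA_integer_, dims)
  voxpos[idx] <- seq_along(idx)
  fwhm <- numeric(3)
  for (a in 1:3) {
    nb <- arr_idx
    nb[, a] <- nb[, a] + 1L
    inside <- nb[, a] <= dims[a]
    nb_lin <- voxpos[nb[inside, , drop = FALSE]]
    here <- which(inside)[!is.na(nb_lin)]
    nb_lin <- nb_lin[!is.na(nb_lin)]
    if (!length(here)) stop("mask too thin along axis ", a)
    dU <- U[, nb_lin, drop = FALSE] - U[, here, drop = FALSE]
    lambda <- mean(colSums(dU^2)) / voxel_size_mm[a]^2
    fwhm[a] <- sqrt(4 * log(2) / lambda)
  }
  fwhm
}

# Expected Euler characteristic of a thresholded 3D t-field
# (EC densities for d = 0..3, summed over resel counts).
expected_ec <- function(t, df, resels) {
  f <- (1 + t^2 / df)^(-(df - 1) / 2)
  a <- 4 * log(2)
  rho0 <- stats::pt(t, df, lower.tail = FALSE)
  rho1 <- sqrt(a) / (2 * pi) * f
  rho2 <- a / (2 * pi)^(3 / 2) *
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2) * t * f
  rho3 <- a^(3 / 2) / (2 * pi)^2 * f * ((df - 1) / df * t^2 - 1)
  sum(resels * c(rho0, rho1, rho2, rho3))
}

# resel counts of a mask approximated as a cuboid with the mask's
# bounding-box aspect ratio and its exact volume
resel_counts <- function(mask, voxel_size_mm, fwhm_mm) {
  idx <- arrayInd(which(mask), dim(mask))
  ext_mm <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * voxel_size_mm
  vol_mm3 <- sum(mask) * prod(voxel_size_mm)
  kappa <- (vol_mm3 / prod(ext_mm))^(1 / 3)
  e <- ext_mm * kappa / fwhm_mm             # equivalent cuboid, resel units
  c(R0 = 1,
    R1 = sum(e),
    R2 = e[1] * e[2] + e[1] * e[3] + e[2] * e[3],
    R3 = prod(e))
}

#' Random-field-theory corrected threshold for a t-map
#'
#' Computes resel counts from the mask and the estimated (or supplied)
#' smoothness, solves the expected-Euler-characteristic equation for the
#' two-sided family-wise threshold at level `alpha`, and fills in the
#' significant-voxel mask. With `mode = "voxel-fdr"` a voxel-wise BH
#' threshold on the t-map's p-values is used instead.
#'
#' @param result a `tmap_result` from [fit_voxelwise()].
#' @param alpha family-wise level (default 0.001).
#' @param fwhm_mm optional fixed smoothness (3 reals, mm); estimated from
#'   the stored residuals when omitted.
#' @param mode "rft" (default) or "voxel-fdr".
#' @return The completed `tmap_result` (fields `fwhm_est_mm`, `resels`,
#'   `corrected_threshold`, `significant_mask`, `alpha`).
#' @export
rft_threshold <- function(result, alpha = 0.001, fwhm_mm = NULL,
                          mode = c("rft", "voxel-fdr")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "tmap_result"))
  if (result$df < 10L) stop("need df >= 10 for a stable threshold")
  vx <- result$tmap$voxel_size_mm
  tvals <- result$tmap$data[result$mask]

  if (mode == "voxel-fdr") {
    pv <- 2 * stats::pt(abs(tvals), result$df, lower.tail = FALSE)
    rej <- bh_fdr(pv, alpha)$reject
    thr <- if (any(rej)) min(abs(tvals)[rej]) else Inf
    result$corrected_threshold <- thr
  } else {
    if (is.null(fwhm_mm)) {
      if (is.null(result$residuals))
        stop("no residuals stored; supply fwhm_mm")
      fwhm_mm <- estimate_fwhm(result$residuals, result$mask, vx)
    }
    result$fwhm_est_mm <- fwhm_mm
    resels <- resel_counts(result$mask, vx, fwhm_mm)
    result$resels <- resels[["R3"]]
    # two-sided: each tail gets alpha/2 of the expected EC
    g <- function(t) expected_ec(t, result$df, resels) - alpha / 2
    lo <- stats::qt(alpha / 2, result$df, lower.tail = FALSE)
    hi <- 50
    if (!is.finite(g(lo)) || !is.finite(g(hi)) || g(hi) > 0)
      stop("numerical error solving the EC threshold (diagnostics: df=",
           result$df, ", resels=", round(resels[["R3"]], 2), ")")
    thr <- stats::uniroot(g, c(lo, hi), tol = 1e-8)$root
    result$corrected_threshold <- thr
  }
  sig <- array(FALSE, dim(result$tmap$data))
  sig[result$mask] <- abs(tvals) >= result$corrected_threshold
  result$significant_mask <- sig
  result$alpha <- alpha
  result$mode <- mode
  result
}

#' @export
print.tmap_result <- function(x, ...) {
  cat(sprintf("<tmap_result> df = %d, %d in-mask voxels\n",
              x$df, sum(x$mask)))
  if (!is.null(x$corrected_threshold)) {
    cat(sprintf("  %s threshold at alpha = %g: |t| >= %.3f (%d significant voxels)\n",
                if (identical(x$mode, "voxel-fdr")) "voxel-FDR" else "RFT",
                x$alpha, x$corrected_threshold, sum(x$significant_mask)))
    if (!is.null(x$fwhm_est_mm))
      cat(sprintf("  FWHM = %s mm, resels = %.1f\n",
                  paste(round(x$fwhm_est_mm, 2), collapse = " x "),
                  x$resels))
  }
  invisible(x)
}
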