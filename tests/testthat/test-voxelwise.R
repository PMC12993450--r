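# Voxel-wise GLM, smoothness estimation, RFT threshold.

make_vols <- function(mat, dims, vx = c(2, 2, 2)) {
  lapply(seq_len(nrow(mat)), function(i)
    scalar_volume(array(mat[i, ], dims), vx))
}

test_that("voxelwise t agrees with per-voxel lm to 1e-8 on a toy grid", {
  set.seed(20)
  n <- 15; dims <- c(8, 8, 8); V <- prod(dims)
  Y <- matrix(rnorm(n * V), n, V)
  coh <- data.frame(x = rnorm(n), age = rnorm(n))
  des <- design_matrix(coh, "x", "age")
  mask <- array(TRUE, dims)
  tm <- fit_voxelwise(make_vols(Y, dims), des, mask)
  for (v in c(1, 77, 300, 512)) {
    fit <- summary(lm(Y[, v] ~ coh$x + coh$age))
    expect_equal(tm$tmap$data[v], fit$coefficients["coh$x", "t value"],
                 tolerance = 1e-8)
  }
  expect_equal(tm$df, n - 3)
})

test_that("an exact linear voxel is capped; zero-variance voxels flagged", {
  n <- 12; dims <- c(4, 4, 4)
  coh <- data.frame(x = rnorm(n))
  Y <- matrix(rnorm(n * prod(dims)), n)
  Y[, 1] <- 2 * coh$x            # exact fit, non-zero effect
  Y[, 2] <- 5                    # constant outcome
  tm <- fit_voxelwise(make_vols(Y, dims), design_matrix(coh, "x"),
                      array(TRUE, dims))
  expect_gte(abs(tm$tmap$data[1]), 1e6)
  expect_equal(tm$tmap$data[2], 0)
  expect_gte(tm$n_degenerate, 2)
})

test_that("null in-mask t values follow the t distribution", {
  set.seed(21)
  n <- 40; dims <- c(8, 8, 8)
  Y <- matrix(rnorm(n * prod(dims)), n)
  coh <- data.frame(x = rnorm(n))
  tm <- fit_voxelwise(make_vols(Y, dims), design_matrix(coh, "x"),
                      array(TRUE, dims))
  ks <- ks.test(tm$tmap$data, function(q) pt(q, tm$df))
  expect_gt(ks$p.value, 0.01)
})

test_that("negating the contrast flips the map; orthogonal covariates leave t near-unchanged", {
  set.seed(22)
  n <- 24; dims <- c(6, 6, 6)
  Y <- matrix(rnorm(n * prod(dims)), n)
  coh <- data.frame(x = rnorm(n))
  mask <- array(TRUE, dims)
  d1 <- design_matrix(coh, "x")
  d2 <- design_matrix(coh, "x", contrast = c(0, -1))
  t1 <- fit_voxelwise(make_vols(Y, dims), d1, mask)$tmap$data
  t2 <- fit_voxelwise(make_vols(Y, dims), d2, mask)$tmap$data
  expect_equal(t2, -t1, tolerance = 1e-12)

  # covariate orthogonal to both predictor and outcome: only df changes
  z <- residualize(rnorm(n), coh$x)
  Yp <- Y - outer(rep(1, n), colMeans(Y))
  Yo <- Y - z %*% (t(z) %*% Y) / sum(z^2)   # orthogonalize outcome to z
  coh$z <- z
  ta <- fit_voxelwise(make_vols(Yo, dims), design_matrix(coh, "x"), mask)
  tb <- fit_voxelwise(make_vols(Yo, dims), design_matrix(coh, "x", "z"), mask)
  ratio <- ta$tmap$data / tb$tmap$data
  adj <- sqrt(ta$df / tb$df)
  expect_equal(ratio[is.finite(ratio)],
               rep(adj, sum(is.finite(ratio))), tolerance = 1e-6)
})

test_that("rank-deficient designs and grid mismatches error", {
  n <- 12; dims <- c(4, 4, 4)
  coh <- data.frame(x = rnorm(n))
  coh$y <- 2 * coh$x
  expect_error(design_matrix(coh, c("x", "y")), "rank deficient")
  vols <- make_vols(matrix(rnorm(n * prod(dims)), n), dims)
  vols[[3]] <- scalar_volume(array(0, c(5, 4, 4)), 2)
  expect_error(fit_voxelwise(vols, design_matrix(coh, "x"),
                             array(TRUE, dims)), "grid mismatch")
  expect_error(fit_voxelwise(vols[1:11], design_matrix(coh, "x"),
                             array(TRUE, dims)), "match design rows")
})

test_that("fwhm estimator recovers applied smoothing and scales with it", {
  set.seed(23)
  dims <- c(24, 24, 24); vx <- c(2, 2, 2); pad <- 6
  pdims <- dims + 2 * pad
  mask <- array(TRUE, dims)
  smooth_field <- function(fwhm) {
    arr <- ventmark:::gauss_smooth_3d(array(rnorm(prod(pdims)), pdims),
                                      rep(fwhm / 2.355 / 2, 3))
    arr[pad + 1:dims[1], pad + 1:dims[2], pad + 1:dims[3]]
  }
  res8 <- t(replicate(8, as.vector(smooth_field(8))))
  est8 <- estimate_fwhm(res8, mask, vx)
  expect_true(all(abs(est8 - 8) / 8 < 0.15))
  # unsmoothed white noise: estimate near the voxel scale
  res0 <- matrix(rnorm(8 * prod(dims)), 8)
  est0 <- estimate_fwhm(res0, mask, vx)
  expect_true(all(est0 < 2 * vx))
  # doubling the kernel roughly doubles the estimate
  est16 <- estimate_fwhm(t(replicate(8, as.vector(smooth_field(16)))), mask, vx)
  expect_true(all(est16 / est8 > 1.7 & est16 / est8 < 2.3))
  expect_error(estimate_fwhm(res0[1:2, ], mask, vx), ">= 3")
})

test_that("rft threshold raises the bar but beats Bonferroni for smooth fields", {
  set.seed(24)
  n <- 60; dims <- c(32, 32, 32); vx <- c(2, 2, 2)
  Y <- matrix(rnorm(n * prod(dims)), n)
  tm <- fit_voxelwise(make_vols(Y, dims, vx),
                      design_matrix(data.frame(x = rnorm(n)), "x"),
                      array(TRUE, dims))
  alpha <- 0.05
  tm8 <- rft_threshold(tm, alpha = alpha, fwhm_mm = c(8, 8, 8))
  uncorr <- qt(1 - alpha / 2, tm$df)
  bonf <- qt(1 - alpha / 2 / prod(dims), tm$df)
  expect_gte(tm8$corrected_threshold, uncorr)
  expect_lt(tm8$corrected_threshold, bonf)
  # monotone in alpha and in resels
  tm_strict <- rft_threshold(tm, alpha = 0.001, fwhm_mm = c(8, 8, 8))
  expect_gt(tm_strict$corrected_threshold, tm8$corrected_threshold)
  tm_rough <- rft_threshold(tm, alpha = alpha, fwhm_mm = c(4, 4, 4))
  expect_gt(tm_rough$corrected_threshold, tm8$corrected_threshold)
  expect_true(all(abs(tm8$tmap$data[tm8$significant_mask]) >=
                    tm8$corrected_threshold))
})

test_that("voxel-fdr mode applies a BH threshold on voxel p-values", {
  set.seed(25)
  n <- 20; dims <- c(8, 8, 8)
  coh <- data.frame(x = rnorm(n))
  Y <- matrix(rnorm(n * prod(dims)), n)
  Y[, 1:20] <- Y[, 1:20] + outer(coh$x, rep(4, 20))
  tm <- fit_voxelwise(make_vols(Y, dims), design_matrix(coh, "x"),
                      array(TRUE, dims))
  fdr <- rft_threshold(tm, alpha = 0.05, mode = "voxel-fdr")
  pv <- 2 * pt(abs(tm$tmap$data), tm$df, lower.tail = FALSE)
  expect_identical(sum(fdr$significant_mask),
                   sum(bh_fdr(as.vector(pv), 0.05)$reject))
})
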