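# Z-scores, ANOVA/Tukey/BH, Spearman, standardized OLS.

test_that("zscores_vs_reference normalizes by the reference subgroup", {
  set.seed(8)
  x <- rnorm(60, 5, 2)
  ref <- rep(c(TRUE, FALSE), 30)
  z <- zscores_vs_reference(x, ref)
  expect_equal(mean(z[ref]), 0, tolerance = 1e-10)
  expect_equal(sd(z[ref]), 1, tolerance = 1e-10)
  expect_equal(z, (x - mean(x[ref])) / sd(x[ref]), tolerance = 1e-12)
  # a non-reference value equal to the reference mean scores 0
  z2 <- zscores_vs_reference(c(x, mean(x[ref])), c(ref, FALSE))
  expect_equal(z2[61], 0)
  # affine invariance
  expect_equal(zscores_vs_reference(3 * x - 7, ref), z, tolerance = 1e-10)
  expect_error(zscores_vs_reference(x, rep(FALSE, 60)), "reference")
  expect_error(zscores_vs_reference(rep(c(1, 1, 2), 20),
                                    c(TRUE, TRUE, rep(FALSE, 58))),
               "zero spread")
})

test_that("one-way ANOVA F-statistic matches a hand-rolled oracle", {
  set.seed(10)
  g <- rep(c("a", "b", "c"), c(12, 15, 9))
  y <- rnorm(36) + (g == "c") * 0.8
  res <- oneway_anova_tukey(y, g)
  # closed-form one-way F oracle
  gm <- mean(y); k <- 3; n <- length(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$f_stat, f_oracle, tolerance = 1e-8)
  expect_equal(unname(res$df), c(2, 33))
  expect_equal(nrow(res$pairwise), 3)
})

test_that("two-group Tukey p equals the studentized-range/t equivalence", {
  set.seed(11)
  y <- c(rnorm(14), rnorm(16, 0.7))
  g <- rep(c("a", "b"), c(14, 16))
  res <- oneway_anova_tukey(y, g)
  # oracle: equal-variance two-sample t, Tukey p = P(Q > sqrt(2)|t|)
  tt <- t.test(y ~ g, var.equal = TRUE)
  p_oracle <- ptukey(sqrt(2) * abs(tt$statistic), 2, 28, lower.tail = FALSE)
  expect_equal(res$pairwise$tukey_p, unname(p_oracle), tolerance = 1e-8)
})

test_that("group separation and null behaviour of the pairwise family", {
  set.seed(12)
  y0 <- rnorm(45); g <- rep(c("a", "b", "c"), 15)
  null_res <- oneway_anova_tukey(y0, g)
  expect_true(all(null_res$pairwise$fdr_adjusted_p > 0.2))
  expect_false(any(null_res$pairwise$reject))
  y1 <- y0 + (g == "b") * 10 * sd(y0)
  sep <- oneway_anova_tukey(y1, g)
  bpairs <- sep$pairwise$groupA == "b" | sep$pairwise$groupB == "b"
  expect_true(all(sep$pairwise$reject[bpairs]))
  expect_error(oneway_anova_tukey(rep(1, 45), g), "identical")
  expect_warning(oneway_anova_tukey(rnorm(20), rep(c("a", "b", "c"), c(10, 9, 1))),
                 "n < 2")
  expect_warning(oneway_anova_tukey(rnorm(24), rep(c("a", "b", "c"), c(10, 10, 4))),
                 "low-n")
})

test_that("bh_fdr implements the step-up rule", {
  # enumerated step-up oracle: p_(i) <= i q / m
  expect_true(all(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)$reject))
  expect_false(any(bh_fdr(rep(1, 6))$reject))
  expect_true(bh_fdr(0.05, 0.05)$reject)
  expect_false(bh_fdr(0.051, 0.05)$reject)
  set.seed(13)
  for (r in 1:10) {
    p <- runif(15)^2
    got <- bh_fdr(p, 0.05)
    # independent step-up oracle
    m <- length(p); o <- order(p)
    k <- max(c(0, which(p[o] <= seq_len(m) * 0.05 / m)))
    rej_oracle <- logical(m)
    if (k > 0) rej_oracle[o[seq_len(k)]] <- TRUE
    expect_identical(got$reject, rej_oracle)
    # adjusted values monotone in sorted order, capped at 1
    expect_true(all(diff(got$adjusted[o]) >= -1e-15))
    expect_true(all(got$adjusted <= 1))
    # Bonferroni rejections are a subset of BH rejections
    expect_true(all(which(p <= 0.05 / m) %in% which(got$reject)))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("spearman_cor matches rank-then-Pearson with ties", {
  set.seed(14)
  x <- sample(1:6, 40, replace = TRUE)
  y <- sample(1:5, 40, replace = TRUE)
  got <- spearman_cor(x, y)
  oracle <- cor(rank(x), rank(y))      # average ranks for ties
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  t_or <- oracle * sqrt(38 / (1 - oracle^2))
  expect_equal(got$p, 2 * pt(abs(t_or), 38, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearman_cor(rep(1, 10), 1:10), "constant")
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
})

test_that("ols_standardized matches the normal-equations oracle", {
  set.seed(15)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), age = rnorm(n, 60, 8),
                  sex = rbinom(n, 1, 0.5))
  d$y <- 0.5 * d$x1 - 0.3 * d$x2 + 0.02 * d$age + rnorm(n)
  res <- ols_standardized(d, "y", c("x1", "x2"), c("age", "sex"))
  # normal-equations oracle on the standardized design
  sc <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(1, sc(d$x1), sc(d$x2), sc(d$age), d$sex - mean(d$sex))
  beta <- solve(t(X) %*% X, t(X) %*% sc(d$y))
  expect_equal(unname(res$beta_std), beta[2:5], tolerance = 1e-10)
  expect_true(all(res$ci95[, 1] <= res$beta_std & res$beta_std <= res$ci95[, 2]))
  expect_gte(res$r2, 0); expect_lte(res$r2, 1)

  # outcome identical to one predictor
  d$y2 <- d$x1
  res2 <- suppressWarnings(ols_standardized(d, "y2", "x1"))
  expect_equal(unname(res2$beta_std["x1"]), 1, tolerance = 1e-10)
  expect_equal(res2$r2, 1, tolerance = 1e-10)
  # independent outcome: small effects, near-zero R2
  set.seed(16)
  d$y3 <- rnorm(n)
  res3 <- ols_standardized(d, "y3", c("x1", "x2"), c("age", "sex"))
  expect_true(all(abs(res3$beta_std) < 0.3))
  expect_lt(res3$r2, 0.1)
  # collinearity names the offending column
  d$x3 <- d$x1
  expect_error(ols_standardized(d, "y", c("x1", "x3")), "x3")
})

test_that("ANOVA p-values are uniform under a simulated global null", {
  set.seed(17)
  sizes <- c(52, 166, 64, 4, 92)
  g <- factor(rep(letters[1:5], sizes))
  pvals <- replicate(400, {
    y <- rnorm(sum(sizes))
    summary(aov(y ~ g))[[1]][["Pr(>F)"]][1]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  # BH family-wise false rejection proportion stays near q
  q <- 0.05
  fr <- replicate(400, {
    y <- rnorm(sum(sizes))
    res <- suppressWarnings(oneway_anova_tukey(y, g, q = q))
    any(res$pairwise$reject)
  })
  se <- sqrt(q * (1 - q) / 400)
  expect_lte(mean(fr), q + 3 * se)
})
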