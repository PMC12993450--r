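# PET quantification: masking, smoothing, SUVR, VR mask, staging.

test_that("mask_meninges zeroes only meningeal voxels", {
  lm_ <- anatomy_labels()
  set.seed(2)
  arr <- array(sample(c(0L, lm_[["white_matter"]], lm_[["meninges"]]),
                      6^3, replace = TRUE), c(6, 6, 6))
  lab <- label_volume(arr, 1)
  vol <- scalar_volume(array(rnorm(6^3), c(6, 6, 6)), 1)
  out <- mask_meninges(vol, lab)
  men <- arr == lm_[["meninges"]]
  expect_true(all(out$data[men] == 0))
  expect_identical(out$data[!men], vol$data[!men])

  nomen <- lab; nomen$data[men] <- lm_[["white_matter"]]
  expect_identical(mask_meninges(vol, nomen)$data, vol$data)
  allmen <- lab; allmen$data[] <- lm_[["meninges"]]
  expect_true(all(mask_meninges(vol, allmen)$data == 0))
  bad <- scalar_volume(array(0, c(5, 6, 6)), 1)
  expect_error(mask_meninges(bad, lab), "grid mismatch")
})

test_that("smooth_to_fwhm has the requested impulse response width", {
  dims <- c(33, 33, 33)
  arr <- array(0, dims); arr[17, 17, 17] <- 1
  sm <- smooth_to_fwhm(scalar_volume(arr, 2), 8)
  prof <- sm$data[, 17, 17]
  half <- max(prof) / 2
  width_mm <- sum(prof >= half) * 2
  expect_lte(abs(width_mm - 8), 2)        # 8 mm +/- 1 voxel

  v <- scalar_volume(array(rnorm(prod(dims)), dims), 2)
  expect_identical(smooth_to_fwhm(v, 0)$data, v$data)
  const <- scalar_volume(array(3.7, dims), 2)
  expect_equal(smooth_to_fwhm(const, 8)$data, const$data, tolerance = 1e-12)
  # reflective boundaries approximately preserve the global mean
  expect_lt(abs(mean(smooth_to_fwhm(v, 8)$data) / mean(v$data) - 1), 1e-3)
  expect_error(smooth_to_fwhm(v, -1), "fwhm")
})

test_that("suvr is the mean ratio and is scale invariant", {
  set.seed(3)
  dims <- c(8, 8, 8)
  vol <- scalar_volume(array(runif(prod(dims), 0.5, 3), dims), 1)
  tgt <- array(FALSE, dims); tgt[1:4, , ] <- TRUE
  ref <- array(FALSE, dims); ref[5:8, , ] <- TRUE
  # brute-force voxel-loop oracle
  s1 <- 0; n1 <- 0; s2 <- 0; n2 <- 0
  for (i in seq_along(vol$data)) {
    if (tgt[i]) { s1 <- s1 + vol$data[i]; n1 <- n1 + 1 }
    if (ref[i]) { s2 <- s2 + vol$data[i]; n2 <- n2 + 1 }
  }
  expect_equal(suvr(vol, tgt, ref), (s1 / n1) / (s2 / n2), tolerance = 1e-12)

  uni <- scalar_volume(array(2.2, dims), 1)
  expect_equal(suvr(uni, tgt, ref), 1.0)
  k <- 3.3; scaled <- vol; scaled$data <- k * vol$data
  expect_equal(suvr(scaled, tgt, ref), suvr(vol, tgt, ref), tolerance = 1e-12)
  two <- vol; two$data[tgt] <- 3.1; two$data[ref] <- 2.0
  expect_equal(suvr(two, tgt, ref), 1.55)
  expect_error(suvr(vol, array(FALSE, dims), ref), "empty")
  neg <- vol; neg$data[ref] <- -1
  expect_error(suvr(neg, tgt, ref), "reference")
})

test_that("composite_suvr pools member voxels and reduces to suvr", {
  ph <- fixture_phantom()
  lab <- ph$labels; vol <- ph$amyloid
  roi1 <- composite_roi("single", "meta_temporal", "cerebellum_gm")
  expect_equal(composite_suvr(vol, lab, roi1),
               suvr(vol, label_mask(lab, "meta_temporal"),
                    label_mask(lab, "cerebellum_gm")), tolerance = 1e-12)
  roi2 <- composite_roi("pair", c("meta_temporal", "neocortex_composite"),
                        "cerebellum_gm")
  # pooled-voxel oracle
  m <- label_mask(lab, c("meta_temporal", "neocortex_composite"))
  expect_equal(composite_suvr(vol, lab, roi2),
               mean(vol$data[m]) / mean(vol$data[label_mask(lab, "cerebellum_gm")]),
               tolerance = 1e-12)
  # composite lies between member-wise SUVRs
  s_members <- c(composite_suvr(vol, lab, roi1),
                 composite_suvr(vol, lab, composite_roi(
                   "x", "neocortex_composite", "cerebellum_gm")))
  expect_gte(composite_suvr(vol, lab, roi2), min(s_members))
  expect_lte(composite_suvr(vol, lab, roi2), max(s_members))
  expect_error(composite_suvr(vol, lab, composite_roi("bad", "nope", "cerebellum_gm")),
               "unknown region")
  expect_error(composite_roi("bad", "a", "a"), "disjoint")
})

test_that("make_vr_mask excludes plexus and erodes by a voxel ball", {
  ph <- fixture_phantom()
  lab <- ph$labels
  vent <- label_mask(lab, c("lateral_ventricle_L", "lateral_ventricle_R"))
  cp <- label_mask(lab, c("choroid_plexus_L", "choroid_plexus_R"))
  m0 <- make_vr_mask(lab, erosion_mm = 0)
  expect_identical(m0, vent & !cp)
  m2 <- make_vr_mask(lab, erosion_mm = 2)
  expect_false(any(m2 & cp))
  expect_true(all(m2[vent] | !m2[vent]))  # subset of ventricles
  expect_true(all(which(m2) %in% which(vent)))
  expect_lt(sum(m2), sum(m0))
  # 2 mm erosion on 2 mm voxels equals the 1-voxel-ball erosion oracle
  sub <- m0[30:60, 30:70, 35:60]
  expect_identical(ventmark:::erode_ball(sub, 1), oracle_erode(sub, 1))
})

test_that("binary erosion matches the voxel-loop oracle on random masks", {
  set.seed(4)
  for (r in 1:6) {
    m <- array(runif(10 * 9 * 8) > 0.35, c(10, 9, 8))
    expect_identical(ventmark:::erode_ball(m, 1), oracle_erode(m, 1))
    expect_identical(ventmark:::erode_ball(m, 1.8), oracle_erode(m, 1.8))
  }
})

test_that("vr mask size strictly decreases with erosion until empty", {
  lab <- fixture_phantom()$labels
  sizes <- c(sum(make_vr_mask(lab, 0)), sum(make_vr_mask(lab, 2)))
  expect_true(all(diff(sizes) < 0))
  expect_error(make_vr_mask(lab, 12), "degenerate mask")
})

test_that("vr_suvr recovers reference level and scales linearly", {
  lab <- fixture_phantom()$labels
  dims <- dim(lab$data)
  flat <- scalar_volume(array(2.5, dims), lab$voxel_size_mm, "amyloid")
  expect_equal(vr_suvr(flat, lab), 1.0)
  set.seed(6)
  vol <- scalar_volume(array(runif(prod(dims), 0.5, 2), dims),
                       lab$voxel_size_mm, "amyloid")
  v1 <- vr_suvr(vol, lab)
  vent <- make_vr_mask(lab, 2)
  vol2 <- vol; vol2$data[vent] <- 2 * vol$data[vent]
  expect_equal(vr_suvr(vol2, lab), 2 * v1, tolerance = 1e-10)
})

test_that("A/T staging uses strict cutoffs and is self-consistent on printed group means", {
  expect_identical(classify_at(2.47, 2.33)$stage_label, "A+T+")
  expect_identical(classify_at(1.25, 0.92)$stage_label, "A-T-")
  expect_identical(classify_at(1.55, 1.18)$stage_label, "A-T-")  # ties negative
  # the four labelled groups' mean SUVRs classify into their own labels
  printed <- list("A-T-" = c(1.25, 0.92), "A+T-" = c(2.04, 0.99),
                  "A-T+" = c(1.36, 3.19), "A+T+" = c(2.47, 2.33))
  for (lbl in names(printed))
    expect_identical(classify_at(printed[[lbl]][1], printed[[lbl]][2])$stage_label,
                     lbl)
  expect_error(classify_at(NA_real_, 1), "finite")
})
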