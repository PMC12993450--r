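# Volumetric biomarkers: region volumes, ICV, residualization, Evans' Index

#' Volume of a labelled region
#'
#' Voxel count of the named region times the physical voxel volume.
#'
#' @param labels a `label_volume`.
#' @param region a label name present in the volume's label map (a vector
#'   of names gives the volume of the union).
#' @return Volume in mm^3 (0 when no voxel carries the label).
#' @export
region_volume <- function(labels, region) {
  m <- label_mask(labels, region)
  sum(m) * voxel_volume_mm3(labels)
}

#' Intracranial volume
#'
#' Total volume of all non-background voxels (the head interior including
#' the meningeal rim), in mm^3.
#'
#' @param labels a `label_volume`.
#' @return ICV in mm^3.
#' @export
icv <- function(labels) {
  n <- sum(labels$data != 0L)
  if (n == 0L) stop("degenerate input: volume contains no non-background voxels")
  n * voxel_volume_mm3(labels)
}

#' Residualize a biomarker against a covariate
#'
#' Ordinary least-squares residuals of `values` on an intercept plus
#' `covariate`; used to correct ventricular and choroid plexus volumes for
#' intracranial volume before Z-scoring and correlation.
#'
#' @param values numeric vector.
#' @param covariate numeric vector of the same length.
#' @return Residual vector (sums to zero, orthogonal to the covariate).
#' @export
residualize <- function(values, covariate) {
  if (length(values) != length(covariate) || length(values) < 3L)
    stop("values and covariate must have equal length >= 3")
  if (stats::sd(covariate) == 0)
    stop("rank deficiency: covariate is constant")
  stats::lm.fit(cbind(1, covariate), values)$residuals
}

#' Evans' Index from a label volume
#'
#' Ratio of the maximal frontal-horn width of the lateral ventricles to the
#' internal skull diameter. The horn width is the maximum left-right extent
#' of ventricle voxels over axial slices, restricted to the anterior third
#' of the ventricles' own anterior-posterior extent; width on a slice is
#' (max x index - min x index + 1) * voxel size, without sub-voxel
#' interpolation. The skull diameter is by default the global maximum
#' left-right extent of the head interior over all axial slices; setting
#' `same_slice = TRUE` instead measures it on the slice where the maximal
#' horn width occurs.
#'
#' @param labels a `label_volume` with lateral ventricles and a non-empty
#'   head interior.
#' @param same_slice measure the skull diameter on the horn slice rather
#'   than globally (default `FALSE`).
#' @return An object of class `evans_result` with fields `ei`,
#'   `horn_width_mm`, `skull_diameter_mm`, `horn_slice_index`.
#' @export
evans_index <- function(labels, same_slice = FALSE) {
  vx <- labels$voxel_size_mm[1]
  vent <- label_mask(labels, c("lateral_ventricle_L", "lateral_ventricle_R"))
  if (!any(vent)) stop("degenerate input: empty ventricle mask")
  head <- labels$data != 0L
  if (!any(head)) stop("degenerate input: empty head interior")

  idx <- which(vent, arr.ind = TRUE)
  ylo_all <- min(idx[, 2]); yhi <- max(idx[, 2])
  extent_y <- yhi - ylo_all + 1L
  # anterior third of the ventricles' own y-extent (+y = anterior)
  y_cut <- yhi - ceiling(extent_y / 3) + 1L
  ant <- idx[idx[, 2] >= y_cut, , drop = FALSE]

  # per axial slice (fixed z): left-right extent of anterior ventricle voxels
  horn_w <- 0; horn_z <- NA_integer_
  for (z in sort(unique(ant[, 3]))) {
    xs <- ant[ant[, 3] == z, 1]
    w <- (max(xs) - min(xs) + 1L) * vx
    if (w > horn_w) { horn_w <- w; horn_z <- z }
  }

  hidx <- which(head, arr.ind = TRUE)
  if (isTRUE(same_slice)) hidx <- hidx[hidx[, 3] == horn_z, , drop = FALSE]
  skull_w <- 0
  for (z in sort(unique(hidx[, 3]))) {
    xs <- hidx[hidx[, 3] == z, 1]
    w <- (max(xs) - min(xs) + 1L) * vx
    if (w > skull_w) skull_w <- w
  }

  structure(list(ei = horn_w / skull_w,
                 horn_width_mm = horn_w,
                 skull_diameter_mm = skull_w,
                 horn_slice_index = horn_z),
            class = "evans_result")
}

#' @export
print.evans_result <- function(x, ...) {
  cat(sprintf("Evans' Index: %.3f (horn %.1f mm / skull %.1f mm, slice z=%d)\n",
              x$ei, x$horn_width_mm, x$skull_diameter_mm, x$horn_slice_index))
  invisible(x)
}

#' Exclude participants with disproportionate ventriculomegaly
#'
#' Computes the Evans' Index per participant and drops those strictly above
#' the threshold (default 0.3), mirroring the screening rule used to remove
#' hydrocephalus-like ventricular enlargement before analysis.
#'
#' @param cohort data frame with an `id` column.
#' @param phantoms named list of `phantom_bundle` objects (or bare
#'   `label_volume`s), names matching `cohort$id`.
#' @param threshold exclusion threshold on EI (strict inequality).
#' @return List with `cohort` (retained rows, plus an `ei` column) and
#'   `report` (data frame of excluded id / ei, and the exclusion count).
#' @export
apply_ei_exclusion <- function(cohort, phantoms, threshold = 0.3) {
  stopifnot(is.data.frame(cohort), all(cohort$id %in% names(phantoms)))
  ei <- vapply(cohort$id, function(i) {
    ph <- phantoms[[i]]
    lab <- if (inherits(ph, "label_volume")) ph else ph$labels
    evans_index(lab)$ei
  }, numeric(1))
  cohort$ei <- unname(ei)
  drop <- cohort$ei > threshold
  list(cohort = cohort[!drop, , drop = FALSE],
       report = list(excluded = data.frame(id = cohort$id[drop],
                                           ei = cohort$ei[drop]),
                     n_excluded = sum(drop),
                     threshold = threshold))
}

#' Grey-matter volume of a phantom
#'
#' Sum of all grey-matter compartments (generic ribbon, neocortical
#' composite, temporal meta-region, cerebellar grey matter), in mm^3; used
#' as a neurodegeneration covariate in voxel-wise models.
#'
#' @param labels a `label_volume`.
#' @return Volume in mm^3.
#' @export
grey_matter_volume <- function(labels) {
  region_volume(labels, c("grey_matter", "neocortex_composite",
                          "meta_temporal", "cerebellum_gm"))
}
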