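# PET quantification: meninges masking, smoothing, SUVR, ventricular
# radioactivity, A/T staging.

#' Zero out meningeal signal
#'
#' Sets meninges-labelled voxels to 0. Applied before smoothing so that
#' meningeal tracer binding cannot spill into adjacent cortex.
#'
#' @param volume a `scalar_volume`.
#' @param labels a co-registered `label_volume` with a meninges label.
#' @return A `scalar_volume` with meningeal voxels zeroed.
#' @export
mask_meninges <- function(volume, labels) {
  if (!same_grid(volume, labels)) stop("grid mismatch between volume and labels")
  m <- label_mask(labels, "meninges")
  out <- volume
  out$data[m] <- 0
  out
}

#' Gaussian smoothing to a target FWHM
#'
#' Separable Gaussian smoothing with per-axis sigma =
#' fwhm / (2*sqrt(2*log(2))) / voxel_size, reflective boundary handling.
#' `fwhm_mm = 0` is the identity.
#'
#' @param volume a `scalar_volume`.
#' @param fwhm_mm target full width at half maximum in mm (default 8).
#' @return Smoothed `scalar_volume`.
#' @export
smooth_to_fwhm <- function(volume, fwhm_mm = 8) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / volume$voxel_size_mm
  out <- volume
  out$data <- gauss_smooth_3d(volume$data, sigma_vox)
  out
}

#' Standardized uptake value ratio over explicit masks
#'
#' Mean signal over the target mask divided by mean signal over the
#' reference mask.
#'
#' @param volume a `scalar_volume`.
#' @param target_mask,reference_mask logical 3D arrays on the same grid.
#' @return SUVR (scalar).
#' @export
suvr <- function(volume, target_mask, reference_mask) {
  if (!any(target_mask)) stop("empty target mask")
  if (!any(reference_mask)) stop("empty reference mask")
  ref <- mean(volume$data[reference_mask])
  if (ref <= 0) stop("quantification error: non-positive reference mean")
  mean(volume$data[target_mask]) / ref
}

#' Composite-region SUVR
#'
#' Volume-weighted mean over the union of the member labels, divided by the
#' reference-region mean. The default composites mirror the neocortical
#' amyloid composite and the temporal tau meta-region, with the cerebellar
#' grey matter as reference.
#'
#' @param volume a `scalar_volume`.
#' @param labels a co-registered `label_volume`.
#' @param roi a list with `members` (character vector of label names) and
#'   `reference` (single label name); see [composite_roi()].
#' @return SUVR (scalar).
#' @export
composite_suvr <- function(volume, labels, roi) {
  if (!same_grid(volume, labels)) stop("grid mismatch between volume and labels")
  suvr(volume,
       target_mask = label_mask(labels, roi$members),
       reference_mask = label_mask(labels, roi$reference))
}

#' Define a composite ROI
#'
#' @param name composite name.
#' @param members non-empty character vector of member label names.
#' @param reference reference label name, disjoint from the members.
#' @return A `composite_roi` list.
#' @export
composite_roi <- function(name, members, reference) {
  if (!length(members)) stop("composite must have at least one member")
  if (reference %in% members) stop("reference must be disjoint from members")
  structure(list(name = name, members = members, reference = reference),
            class = "composite_roi")
}

#' Built-in composite definitions
#'
#' `"neocortex"`: neocortical amyloid composite referenced to full
#' cerebellar grey matter. `"metatemporal"`: temporal meta-region for tau
#' referenced to (inferior) cerebellar grey matter. In the phantom both
#' references map onto the single cerebellar compartment.
#'
#' @param which composite name.
#' @return A `composite_roi`.
#' @export
default_roi <- function(which = c("neocortex", "metatemporal")) {
  which <- match.arg(which)
  switch(which,
    neocortex = composite_roi("neocortex", "neocortex_composite", "cerebellum_gm"),
    metatemporal = composite_roi("metatemporal", "meta_temporal", "cerebellum_gm"))
}

#' Ventricular-radioactivity mask
#'
#' Lateral ventricles minus choroid plexus, then binary erosion by a ball
#' whose voxel radius is `round(erosion_mm / min(voxel size))`; the erosion
#' reduces spill-in from periventricular tissue and the plexus itself.
#'
#' @param labels a `label_volume`.
#' @param erosion_mm erosion radius in mm (default 2).
#' @return Logical 3D mask.
#' @export
make_vr_mask <- function(labels, erosion_mm = 2) {
  vent <- label_mask(labels, c("lateral_ventricle_L", "lateral_ventricle_R"))
  if (!any(vent)) stop("lateral ventricles absent")
  cp <- label_mask(labels, c("choroid_plexus_L", "choroid_plexus_R"))
  m <- vent & !cp
  r <- round(erosion_mm / min(labels$voxel_size_mm))
  if (r > 0) m <- erode_ball(m, r)
  if (!any(m)) {
    stop("degenerate mask: erosion emptied the ventricular mask (ventricle ",
         sum(vent) * voxel_volume_mm3(labels), " mm^3, erosion ", erosion_mm,
         " mm)")
  }
  m
}

#' Ventricular-radioactivity SUVR
#'
#' SUVR over the eroded, plexus-free ventricular mask, referenced to the
#' tracer-appropriate cerebellar region; an indirect proxy of
#' choroid-plexus-related CSF clearance.
#'
#' @param volume a `scalar_volume` with its `tracer` field set.
#' @param labels a co-registered `label_volume`.
#' @param erosion_mm erosion radius in mm (default 2).
#' @param reference reference label name; default cerebellar grey matter.
#' @return SUVR (scalar).
#' @export
vr_suvr <- function(volume, labels, erosion_mm = 2, reference = "cerebellum_gm") {
  if (!same_grid(volume, labels)) stop("grid mismatch between volume and labels")
  suvr(volume,
       target_mask = make_vr_mask(labels, erosion_mm),
       reference_mask = label_mask(labels, reference))
}

#' Amyloid/tau biomarker staging
#'
#' Strict-threshold positivity: amyloid-positive iff neocortical amyloid
#' SUVR > `a_cut`, tau-positive iff temporal meta-region tau SUVR >
#' `t_cut`; ties classify negative.
#'
#' @param abeta_suvr neocortical amyloid SUVR.
#' @param tau_suvr temporal meta-region tau SUVR.
#' @param a_cut amyloid positivity cutoff (default 1.55).
#' @param t_cut tau positivity cutoff (default 1.18).
#' @return List with `a_positive`, `t_positive`, `stage_label`
#'   (one of "A-T-", "A+T-", "A-T+", "A+T+").
#' @export
classify_at <- function(abeta_suvr, tau_suvr, a_cut = 1.55, t_cut = 1.18) {
  if (!is.finite(abeta_suvr) || !is.finite(tau_suvr))
    stop("SUVR inputs must be finite")
  a <- abeta_suvr > a_cut
  t <- tau_suvr > t_cut
  list(a_positive = a, t_positive = t,
       stage_label = paste0("A", if (a) "+" else "-",
                            "T", if (t) "+" else "-"))
}

#' Extract all image-derived biomarkers from one phantom
#'
#' Runs the full per-participant quantification: meninges masking and
#' smoothing of both PET volumes, region volumes, ICV, grey-matter volume,
#' Evans' Index, composite SUVRs, ventricular radioactivity, and A/T stage.
#'
#' @param bundle a `phantom_bundle` from [simulate_phantom()].
#' @param fwhm_mm smoothing target in mm (default 8).
#' @param erosion_mm VR-mask erosion in mm (default 2).
#' @param vr_presmoothing compute VR SUVR on the unsmoothed (masked) volume
#'   instead of the smoothed one (default `FALSE`).
#' @param a_cut,t_cut staging cutoffs.
#' @return One-row data frame of biomarkers.
#' @export
extract_biomarkers <- function(bundle, fwhm_mm = 8, erosion_mm = 2,
                               vr_presmoothing = FALSE,
                               a_cut = 1.55, t_cut = 1.18) {
  lab <- bundle$labels
  am_raw <- mask_meninges(bundle$amyloid, lab)
  ta_raw <- mask_meninges(bundle$tau, lab)
  am <- smooth_to_fwhm(am_raw, fwhm_mm)
  ta <- smooth_to_fwhm(ta_raw, fwhm_mm)

  vv <- region_volume(lab, c("lateral_ventricle_L", "lateral_ventricle_R"))
  cpv <- region_volume(lab, c("choroid_plexus_L", "choroid_plexus_R"))
  icv_ <- icv(lab)
  gm <- grey_matter_volume(lab)
  ei <- evans_index(lab)$ei

  abeta <- composite_suvr(am, lab, default_roi("neocortex"))
  tau <- composite_suvr(ta, lab, default_roi("metatemporal"))
  vr_am <- vr_suvr(if (vr_presmoothing) am_raw else am, lab, erosion_mm)
  vr_ta <- vr_suvr(if (vr_presmoothing) ta_raw else ta, lab, erosion_mm)
  at <- classify_at(abeta, tau, a_cut, t_cut)

  data.frame(id = bundle$truth$id, vv = vv, cpv = cpv, icv = icv_,
             gm_volume = gm, ei = ei,
             abeta_neocortex = abeta, tau_metaroi = tau,
             vr_amyloid = vr_am, vr_tau = vr_ta,
             a_pos = at$a_positive, t_pos = at$t_positive,
             stage = at$stage_label,
             stringsAsFactors = FALSE)
}
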