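# 3D brain phantom generation --------------------------------------------
#
# Each participant gets a pre-aligned geometric phantom: an intracranial
# ellipsoid with a 1-voxel meningeal rim, a cortical ribbon partitioned
# into sector labels (neocortical composite, temporal meta-region, generic
# grey matter), an inferior-posterior cerebellar blob, white-matter
# interior, two lateral ventricles (posterior body + anterior frontal
# horn) scaled to the requested ventricular volume, and choroid plexus
# blobs inside the ventricle bodies. PET volumes are piecewise-constant
# tissue means plus Gaussian noise, constructed so that the quantification
# pipeline recovers the participant's latent biomarker values.

# mm coordinates of voxel centres, origin at the grid centre
grid_coords <- function(grid) {
  lapply(1:3, function(a) {
    n <- grid$shape[a]; v <- grid$voxel_size_mm[a]
    (seq_len(n) - (n + 1) / 2) * v
  })
}

# logical mask of an axis-aligned ellipsoid, via outer sums of squared
# per-axis terms (one pass over the grid)
ellipsoid_mask <- function(coords, centre, semi) {
  u <- ((coords[[1]] - centre[1]) / semi[1])^2
  v <- ((coords[[2]] - centre[2]) / semi[2])^2
  w <- ((coords[[3]] - centre[3]) / semi[3])^2
  nx <- length(u); ny <- length(v); nz <- length(w)
  arr <- array(rep(u, times = ny * nz), c(nx, ny, nz)) +
    array(rep(rep(v, each = nx), times = nz), c(nx, ny, nz)) +
    array(rep(w, each = nx * ny), c(nx, ny, nz))
  arr <= 1
}

# ventricle shape parameters (mm, at unit scale): posterior body plus a
# narrower anterior frontal horn per side. The body's y-extent is fixed
# (scale grows it in x and z only) and it sits posterior enough that the
# anterior third of the ventricles' y-extent always contains only the
# horn, which is what the Evans' Index measures.
.vent_body <- list(centre = c(12, -16, 2), semi = c(8.5, 24, 10.5))
.vent_horn <- list(centre = c(8.5, 18, 4), semi = c(4, 16, 7))
.cp_semi <- c(4, 12, 5)

ventricle_mask <- function(coords, side, s) {
  bsemi <- c(s * .vent_body$semi[1], .vent_body$semi[2], s * .vent_body$semi[3])
  ellipsoid_mask(coords, .vent_body$centre * c(side, 1, 1), bsemi) |
    ellipsoid_mask(coords, .vent_horn$centre * c(side, 1, 1),
                   s * .vent_horn$semi)
}

# monotone bisection of a shape scale so that the voxel count of
# mask_fn(s) & inside matches a target volume; returns the scale whose
# count is closest to the target
fit_scale <- function(mask_fn, inside, target_mm3, vox_mm3,
                      lo = 0.05, hi = 2.2, iter = 22L) {
  count <- function(s) sum(mask_fn(s) & inside) * vox_mm3
  if (count(hi) < target_mm3)
    stop("infeasible geometry: requested volume does not fit (target ",
         round(target_mm3), " mm^3, maximum ", round(count(hi)), " mm^3)")
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (count(mid) < target_mm3) lo <- mid else hi <- mid
  }
  if (abs(count(lo) - target_mm3) < abs(count(hi) - target_mm3)) lo else hi
}

# index range of coords within [lim1, lim2]
crop_range <- function(coords, lim1, lim2) {
  which(coords >= lim1 & coords <= lim2)
}

#' Generate a 3D phantom for one participant
#'
#' Realizes the participant's latent anatomy and PET biomarkers as a label
#' volume plus amyloid and tau SUVR volumes on a common grid. Ventricle
#' and choroid plexus shapes are scaled by bisection so the extracted
#' volumes match the latent values to within voxel quantization (ventricles
#' within ~5%, plexus within ~10%); tissue means are chosen so composite
#' and ventricular SUVRs recover the latent SUVRs before smoothing.
#'
#' @param record one-row data frame (a row of [simulate_cohort()] output)
#'   with `id`, `icv`, `latent_vv`, `latent_cpv`, `latent_vr_amyloid`,
#'   `latent_vr_tau`, `latent_abeta`, `latent_tau`.
#' @param grid a [grid_spec()]; default 96^3 voxels at 2 mm.
#' @param seed integer seed for the PET noise.
#' @param noise_sd SUVR-scale Gaussian noise SD of the PET volumes
#'   (default 0.05).
#' @return A `phantom_bundle`: list with `labels` (`label_volume`),
#'   `amyloid`, `tau` (`scalar_volume`s) and `truth` (the input record).
#' @export
simulate_phantom <- function(record, grid = grid_spec(), seed = 1L,
                             noise_sd = 0.05) {
  stopifnot(nrow(record) == 1L)
  lm_ <- anatomy_labels()
  vox <- prod(grid$voxel_size_mm)
  coords <- grid_coords(grid)
  fov <- grid$shape * grid$voxel_size_mm

  # head ellipsoid from ICV: semi-axes (0.66, 1, 0.80) * r
  ratio <- c(0.66, 1, 0.80)
  r <- (record$icv / (4 / 3 * pi * prod(ratio)))^(1 / 3)
  semi <- ratio * r
  if (any(2 * semi > fov - 4 * grid$voxel_size_mm))
    stop("infeasible geometry: head ellipsoid does not fit the grid")
  head <- ellipsoid_mask(coords, c(0, 0, 0), semi)
  inner <- erode_ball(head, 1)         # head minus the 1-voxel meningeal rim

  lab <- array(0L, grid$shape)
  lab[head] <- lm_["head_interior"]
  lab[head & !inner] <- lm_["meninges"]

  # cortical ribbon: ~3 voxels inside the rim, split into sector labels;
  # a 1-voxel transitional shell below the ribbon keeps the generic
  # head_interior label (unassigned interior tissue)
  shell <- erode_ball(erode_ball(erode_ball(inner, 1), 1), 1)
  deep <- erode_ball(shell, 1)
  ribbon <- inner & !shell
  xs <- coords[[1]]; zs <- coords[[3]]
  X <- array(rep(xs, times = prod(grid$shape[2:3])), grid$shape)
  Z <- array(rep(zs, each = prod(grid$shape[1:2])), grid$shape)
  lateral_inferior <- abs(X) > 0.45 * semi[1] & Z < 0
  lab[ribbon] <- lm_["neocortex_composite"]
  lab[ribbon & lateral_inferior] <- lm_["meta_temporal"]
  lab[ribbon & !lateral_inferior & Z < -0.55 * semi[3]] <- lm_["grey_matter"]
  lab[deep] <- lm_["white_matter"]

  # cerebellum: inferior-posterior blob
  cereb <- ellipsoid_mask(coords, c(0, -0.45 * semi[2], -0.62 * semi[3]),
                          c(0.42, 0.30, 0.28) * semi) & inner
  lab[cereb] <- lm_["cerebellum_gm"]

  # lateral ventricles + choroid plexus, fitted on a cropped subgrid -----
  hi <- 2.6
  xr <- crop_range(coords[[1]],
                   -(.vent_body$centre[1] + hi * .vent_body$semi[1] + 2),
                   .vent_body$centre[1] + hi * .vent_body$semi[1] + 2)
  yr <- crop_range(coords[[2]],
                   .vent_body$centre[2] - .vent_body$semi[2] - 2,
                   .vent_horn$centre[2] + hi * .vent_horn$semi[2] + 2)
  zr <- crop_range(coords[[3]],
                   .vent_body$centre[3] - hi * .vent_body$semi[3] - 2,
                   .vent_body$centre[3] + hi * .vent_body$semi[3] + 2)
  cc <- list(coords[[1]][xr], coords[[2]][yr], coords[[3]][zr])
  deep_c <- deep[xr, yr, zr]

  # the choroid blobs are painted over the ventricle labels afterwards, so
  # the ventricle shape targets the summed ventricle + plexus volume
  target_cp0 <- max(record$latent_cpv, vox)
  vent_fn <- function(s) ventricle_mask(cc, -1, s) | ventricle_mask(cc, 1, s)
  s <- fit_scale(vent_fn, deep_c, record$latent_vv + target_cp0, vox, hi = hi)
  ventL_c <- ventricle_mask(cc, -1, s) & deep_c
  ventR_c <- ventricle_mask(cc, 1, s) & deep_c

  vent_c <- ventL_c | ventR_c
  # choroid blobs: rank ventricle voxels by the plexus ellipsoids'
  # quadratic form and take exactly the target count, so the extracted
  # plexus volume is correct to one voxel
  qform <- function(centre) {
    u <- ((cc[[1]] - centre[1]) / .cp_semi[1])^2
    v <- ((cc[[2]] - centre[2]) / .cp_semi[2])^2
    w <- ((cc[[3]] - centre[3]) / .cp_semi[3])^2
    nx <- length(u); ny <- length(v); nz <- length(w)
    array(rep(u, times = ny * nz), c(nx, ny, nz)) +
      array(rep(rep(v, each = nx), times = nz), c(nx, ny, nz)) +
      array(rep(w, each = nx * ny), c(nx, ny, nz))
  }
  field <- pmin(qform(.vent_body$centre * c(-1, 1, 1)),
                qform(.vent_body$centre))
  vent_idx <- which(vent_c)
  k <- max(1L, min(round(target_cp0 / vox), length(vent_idx) - 1L))
  cp_c <- array(FALSE, dim(vent_c))
  cp_c[vent_idx[order(field[vent_idx])[seq_len(k)]]] <- TRUE

  sub <- lab[xr, yr, zr]
  sub[ventL_c] <- lm_["lateral_ventricle_L"]
  sub[ventR_c] <- lm_["lateral_ventricle_R"]
  sub[cp_c & ventL_c] <- lm_["choroid_plexus_L"]
  sub[cp_c & ventR_c] <- lm_["choroid_plexus_R"]
  lab[xr, yr, zr] <- sub

  labels <- label_volume(lab, grid$voxel_size_mm)

  # PET volumes: piecewise-constant tissue means + Gaussian noise ---------
  ab <- record$latent_abeta; ta <- record$latent_tau
  mean_amyloid <- c(background = 0, grey_matter = 0.2 + 0.8 * ab,
                    white_matter = 1.35,
                    lateral_ventricle_L = record$latent_vr_amyloid,
                    lateral_ventricle_R = record$latent_vr_amyloid,
                    choroid_plexus_L = 1.9, choroid_plexus_R = 1.9,
                    cerebellum_gm = 1.0,
                    meta_temporal = 0.1 + 0.9 * ab,
                    neocortex_composite = ab,
                    meninges = 1.7, head_interior = 1.2)
  mean_tau <- c(background = 0, grey_matter = 0.4 + 0.45 * ta,
                white_matter = 0.9,
                lateral_ventricle_L = record$latent_vr_tau,
                lateral_ventricle_R = record$latent_vr_tau,
                choroid_plexus_L = 1.5, choroid_plexus_R = 1.5,
                cerebellum_gm = 1.0,
                meta_temporal = ta,
                neocortex_composite = 0.5 + 0.45 * ta,
                meninges = 1.3, head_interior = 1.0)
  set.seed(seed)
  paint <- function(means) {
    arr <- array(means[match(as.vector(lab), lm_)], grid$shape)
    arr + stats::rnorm(length(arr), 0, noise_sd) * (lab != 0L)
  }
  amyloid <- scalar_volume(paint(mean_amyloid), grid$voxel_size_mm, "amyloid")
  tau <- scalar_volume(paint(mean_tau), grid$voxel_size_mm, "tau")

  structure(list(labels = labels, amyloid = amyloid, tau = tau,
                 truth = record),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle> participant", x$truth$id, "\n")
  print(x$labels)
  invisible(x)
}

#' Generate phantoms for a whole cohort
#'
#' @param cohort a [simulate_cohort()] table.
#' @param grid a [grid_spec()].
#' @param seed master seed; each participant gets a derived seed.
#' @param noise_sd PET noise SD passed to [simulate_phantom()].
#' @return Named list of `phantom_bundle` objects keyed by participant id.
#' @export
simulate_phantoms <- function(cohort, grid = grid_spec(), seed = 1L,
                              noise_sd = 0.05) {
  out <- vector("list", nrow(cohort))
  names(out) <- cohort$id
  for (i in seq_len(nrow(cohort))) {
    out[[i]] <- simulate_phantom(cohort[i, , drop = FALSE], grid,
                                 seed = derive_seed(seed, i),
                                 noise_sd = noise_sd)
  }
  out
}

# stable per-item seed derivation, kept below 2^31
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 16807) %% 2147483647)
}
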