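# Volume containers -----------------------------------------------------
#
# Two light S3 containers hold all image data: `label_volume` (integer-coded
# segmentation) and `scalar_volume` (PET SUVR maps, t-maps). Both are plain
# 3D arrays with a `voxel_size_mm` attribute so that every downstream
# computation is explicit about physical units.

#' Canonical anatomy label codes
#'
#' Integer codes used by the phantom generator and expected by the
#' volumetric and PET quantification functions. Background is always 0 and
#' the intracranial space is the union of all non-zero labels.
#'
#' @return Named integer vector mapping label names to codes.
#' @export
anatomy_labels <- function() {
  c(background        = 0L,
    grey_matter       = 1L,
    white_matter      = 2L,
    lateral_ventricle_L = 3L,
    lateral_ventricle_R = 4L,
    choroid_plexus_L  = 5L,
    choroid_plexus_R  = 6L,
    cerebellum_gm     = 7L,
    meta_temporal     = 8L,
    neocortex_composite = 9L,
    meninges          = 10L,
    head_interior     = 11L)
}

#' Grid specification for phantom volumes
#'
#' @param shape integer vector of length 3, voxels per axis
#'   (x = left-right, y = posterior-anterior, z = inferior-superior).
#' @param voxel_size_mm numeric vector of length 3 (or scalar), voxel edge
#'   lengths in millimetres. Default isotropic 2 mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape = c(96L, 96L, 96L), voxel_size_mm = c(2, 2, 2)) {
  shape <- as.integer(shape)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(shape) != 3L || any(shape < 16L))
    stop("grid shape must be 3 integers, all >= 16")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel sizes must be 3 positive reals")
  structure(list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "grid_spec")
}

#' Construct a label volume
#'
#' @param data 3D integer array of label codes.
#' @param voxel_size_mm voxel edge lengths in mm (length 3 or scalar).
#' @param label_map named integer vector; defaults to [anatomy_labels()].
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_size_mm = c(2, 2, 2),
                         label_map = anatomy_labels()) {
  if (length(dim(data)) != 3L) stop("label data must be a 3D array")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (anyDuplicated(label_map)) stop("label_map codes must be unique")
  if (any(label_map < 0)) stop("label codes must be non-negative")
  storage.mode(data) <- "integer"
  structure(list(data = data,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 label_map = label_map),
            class = "label_volume")
}

#' Construct a scalar volume
#'
#' @param data 3D numeric array (e.g. SUVR values).
#' @param voxel_size_mm voxel edge lengths in mm (length 3 or scalar).
#' @param tracer one of "amyloid", "tau", "none".
#' @return Object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, voxel_size_mm = c(2, 2, 2),
                          tracer = c("none", "amyloid", "tau")) {
  tracer <- match.arg(tracer)
  if (length(dim(data)) != 3L) stop("scalar data must be a 3D array")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (!all(is.finite(data))) stop("scalar volume must contain finite values")
  storage.mode(data) <- "double"
  structure(list(data = data,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 tracer = tracer),
            class = "scalar_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(x$voxel_size_mm, collapse = "x"), " mm\n", sep = "")
  present <- sort(unique(as.vector(x$data)))
  nm <- names(x$label_map)[match(present, x$label_map)]
  cat("  labels present:", paste(nm, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(x$voxel_size_mm, collapse = "x"),
      " mm, tracer = ", x$tracer, "\n", sep = "")
  cat("  range: [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "]\n", sep = "")
  invisible(x)
}

voxel_volume_mm3 <- function(vol) prod(vol$voxel_size_mm)

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm))
}

#' Binary mask of one or more labels
#'
#' @param labels a `label_volume`.
#' @param region character vector of label names.
#' @return Logical 3D array.
#' @export
label_mask <- function(labels, region) {
  missing_regions <- setdiff(region, names(labels$label_map))
  if (length(missing_regions))
    stop("unknown region name(s): ", paste(missing_regions, collapse = ", "))
  array(labels$data %in% labels$label_map[region], dim(labels$data))
}

# NIfTI I/O --------------------------------------------------------------

#' Read a NIfTI-1 volume
#'
#' Orientation is normalized to RAS and voxel sizes are taken from the
#' header. Integer-valued images are returned as `label_volume` when
#' `as = "label"`, otherwise as `scalar_volume`.
#'
#' @param path file path to a `.nii` or `.nii.gz` file.
#' @param as "scalar" or "label".
#' @param tracer tracer tag for scalar volumes.
#' @param label_map label map for label volumes.
#' @return A `label_volume` or `scalar_volume`.
#' @export
read_volume <- function(path, as = c("scalar", "label"),
                        tracer = "none", label_map = anatomy_labels()) {
  as <- match.arg(as)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, " (", conditionMessage(e), ")"))
  ort <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ort) && !identical(ort, "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  vx <- RNifti::pixdim(img)[seq_len(3L)]
  arr <- array(as.numeric(img), dim(img)[seq_len(3L)])
  if (as == "label") label_volume(round(arr), vx, label_map)
  else scalar_volume(arr, vx, tracer)
}

#' Write a volume as NIfTI-1
#'
#' Writes with a diagonal RAS affine built from the voxel sizes.
#'
#' @param volume a `label_volume` or `scalar_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$data
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
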