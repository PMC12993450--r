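# Shared fixtures and independent oracles for the test suite.

# cached default cohort (cheap) and a few phantoms (dearer)
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(seed = 11L) {
  key <- paste0("cohort", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_cohort(default_params(), seed = seed)
  .fixture_env[[key]]
}

fixture_phantom <- function(row = 1L, seed = 101L, noise_sd = 0.05) {
  key <- paste0("ph", row, "_", seed, "_", noise_sd)
  if (is.null(.fixture_env[[key]])) {
    co <- fixture_cohort()
    .fixture_env[[key]] <- simulate_phantom(co[row, , drop = FALSE],
                                            grid_spec(), seed = seed,
                                            noise_sd = noise_sd)
  }
  .fixture_env[[key]]
}

# hand-built label volume: a rectangular "head" with a ventricle bar whose
# Evans' Index is exactly horn_w / head_w
bar_labels <- function(head_w = 150L, horn_w = 45L, post_w = 11L) {
  lm_ <- anatomy_labels()
  arr <- array(0L, c(160L, 60L, 20L))
  arr[6:(5L + head_w), 10:50, 3:18] <- lm_["head_interior"]
  # ventricle: posterior narrow section y=15..38, anterior horn y=39..44
  x0 <- 80L
  arr[(x0 - post_w %/% 2L):(x0 + post_w %/% 2L), 15:38, 8:12] <-
    lm_["lateral_ventricle_L"]
  arr[(x0 - horn_w %/% 2L):(x0 + horn_w %/% 2L - ((horn_w + 1L) %% 2L)),
      39:44, 8:12] <- lm_["lateral_ventricle_R"]
  label_volume(arr, c(1, 1, 1))
}

# brute-force per-slice Evans' Index oracle: plain loops, no shared code
# with evans_index() beyond the label map
oracle_evans <- function(labels) {
  lm_ <- labels$label_map
  vx <- labels$voxel_size_mm[1]
  d <- dim(labels$data)
  is_vent <- labels$data == lm_["lateral_ventricle_L"] |
    labels$data == lm_["lateral_ventricle_R"]
  ys <- integer(0)
  for (y in seq_len(d[2])) if (any(is_vent[, y, ])) ys <- c(ys, y)
  yhi <- max(ys); ylo <- min(ys)
  y_cut <- yhi - ceiling((yhi - ylo + 1L) / 3) + 1L
  horn <- 0
  for (z in seq_len(d[3])) {
    for_slice <- integer(0)
    for (x in seq_len(d[1]))
      if (any(is_vent[x, y_cut:yhi, z])) for_slice <- c(for_slice, x)
    if (length(for_slice)) {
      w <- (max(for_slice) - min(for_slice) + 1L) * vx
      if (w > horn) horn <- w
    }
  }
  skull <- 0
  nonbg <- labels$data != 0L
  for (z in seq_len(d[3])) {
    xs <- integer(0)
    for (x in seq_len(d[1]))
      if (any(nonbg[x, , z])) xs <- c(xs, x)
    if (length(xs)) {
      w <- (max(xs) - min(xs) + 1L) * vx
      if (w > skull) skull <- w
    }
  }
  horn / skull
}

# voxel-loop binary erosion oracle with an exact Euclidean ball
oracle_erode <- function(mask, radius_vox) {
  d <- dim(mask)
  out <- array(FALSE, d)
  r <- floor(radius_vox)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    keep <- TRUE
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      if (dx^2 + dy^2 + dz^2 > radius_vox^2 + 1e-9) next
      p <- v + c(dx, dy, dz)
      if (any(p < 1L) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        keep <- FALSE; break
      }
    }
    out[v[1], v[2], v[3]] <- keep
  }
  out
}

# random small label volume for volume-counting oracles
random_labels <- function(seed, dims = c(12L, 10L, 8L), vox = c(1.5, 2, 1)) {
  set.seed(seed)
  arr <- array(sample(c(0L, 1L, 3L, 4L), prod(dims), replace = TRUE), dims)
  label_volume(arr, vox)
}
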