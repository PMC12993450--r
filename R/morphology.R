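# Array morphology and separable Gaussian smoothing ----------------------

# Shift a 3D logical array by an integer offset, padding with FALSE.
shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) { src[[a]] <- 1:(d[a] - o); dst[[a]] <- (1 + o):d[a] }
    else        { src[[a]] <- (1 - o):d[a]; dst[[a]] <- 1:(d[a] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    mask[src[[1]], src[[2]], src[[3]]]
  out
}

ball_offsets <- function(radius_vox) {
  r <- as.integer(floor(radius_vox + 1e-9))
  if (r < 0L) stop("radius must be non-negative")
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius_vox^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# Binary erosion by a discrete ball: a voxel survives iff every ball offset
# lands inside the mask (outside the array counts as background).
erode_ball <- function(mask, radius_vox) {
  offs <- ball_offsets(radius_vox)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    if (all(o == 0L)) next
    out <- out & shift_mask(mask, -o)
    if (!any(out)) break
  }
  out
}

dilate_ball <- function(mask, radius_vox) {
  offs <- ball_offsets(radius_vox)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    if (all(o == 0L)) next
    out <- out | shift_mask(mask, o)
  }
  out
}

# Reflective ('symmetric', edge-repeating) index fold into 1..n.
reflect_index <- function(idx, n) {
  period <- 2L * n
  j <- ((idx - 1L) %% period + period) %% period  # 0 .. 2n-1
  ifelse(j < n, j + 1L, period - j)
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-half:half)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# One separable pass along axis `axis` using a dense convolution matrix with
# reflective boundary handling; arr is a 3D array.
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  half <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in (-half):half) {
    rows <- seq_len(n)
    cols <- reflect_index(rows + j, n)
    K[cbind(rows, cols)] <- K[cbind(rows, cols)] + kernel[j + half + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dims <- dim(x)
  y <- K %*% matrix(x, nrow = n)
  dim(y) <- dims
  aperm(y, order(perm))
}

gauss_smooth_3d <- function(arr, sigma_vox) {
  for (a in 1:3) arr <- conv_axis(arr, gauss_kernel(sigma_vox[a]), a)
  arr
}
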