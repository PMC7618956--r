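#' Augmentation configuration
#'
#' Controls the geometric and photometric transforms applied to anchor and
#' positive patches. Positives additionally carry an independent random
#' rotation and a small linear deformation on their sampling grids, so the
#' metric loss sees the same local texture under the full transform family.
#'
#' @param flip_prob probability of flipping a patch along each axis.
#' @param rotation rotation family for positive grids and transformed pairs:
#'   `"uniform"` (uniform over 3D rotations via random quaternions),
#'   `"axis90"` (the 24 axis-aligned rotations) or `"none"`.
#' @param scale_jitter multiplicative physical-size jitter range applied to
#'   positives relative to their anchor's size (clamped to the training size
#'   bounds 4..12).
#' @param r_pos radius (voxels) of the spherical neighbourhood in which
#'   positive centers are drawn around the anchor center.
#' @param deform_range half-width of the uniform perturbation added to the
#'   identity to form the positive grids' shear/scale matrix.
#' @param brightness additive brightness shift range.
#' @param contrast multiplicative contrast range (about the patch mean).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @return an `vxr_augconfig`.
#' @export
augmentation_config <- function(flip_prob = 0.5,
                                rotation = c("uniform", "axis90", "none"),
                                scale_jitter = c(0.9, 1.1),
                                r_pos = 2,
                                deform_range = 0.1,
                                brightness = c(-0.1, 0.1),
                                contrast = c(0.8, 1.25),
                                noise_sd = 0.02) {
  rotation <- match.arg(rotation)
  stopifnot(flip_prob >= 0, flip_prob <= 1, r_pos >= 0, deform_range >= 0,
            all(is.finite(c(scale_jitter, brightness, contrast, noise_sd))))
  structure(list(flip_prob = flip_prob, rotation = rotation,
                 scale_jitter = scale_jitter, r_pos = r_pos,
                 deform_range = deform_range, brightness = brightness,
                 contrast = contrast, noise_sd = noise_sd),
            class = "vxr_augconfig")
}

#' Sampling grids
#'
#' A set of `n` sampling grids, each a 16-points-per-dimension lattice
#' spanning a cube of physical edge `a` (spacing `a/15`) centered on a
#' continuous voxel coordinate, mapped by a 3x3 matrix (rotation times
#' deformation). Stored columnwise for vectorized extraction.
#'
#' @param centers `n x 3` matrix of 0-based `(z, y, x)` centers.
#' @param sizes length-`n` physical edge lengths.
#' @param A `n x 9` matrix of row-major 3x3 transform matrices.
#' @return a `vxr_grids` object.
#' @export
sampling_grids <- function(centers, sizes, A = identity_rows(nrow(centers))) {
  centers <- matrix(centers, ncol = 3)
  stopifnot(length(sizes) == nrow(centers), nrow(A) == nrow(centers), ncol(A) == 9)
  structure(list(centers = centers, sizes = as.numeric(sizes), A = A),
            class = "vxr_grids")
}

#' @export
length.vxr_grids <- function(x) nrow(x$centers)

#' @export
`[.vxr_grids` <- function(x, i) {
  sampling_grids(x$centers[i, , drop = FALSE], x$sizes[i], x$A[i, , drop = FALSE])
}

#' @export
print.vxr_grids <- function(x, ...) {
  cat(sprintf("<vxr_grids n=%d, sizes [%.3g, %.3g]>\n", length(x),
              min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Sample anchor grids uniformly over a volume
#'
#' Anchor centers are uniform over voxels, physical sizes uniform over
#' `size_range`, with identity rotation and no deformation.
#'
#' @param volume a [vxr_volume] or 3D array.
#' @param n number of anchors (> 0).
#' @param size_range `(min, max)` physical edge lengths; the training default
#'   is 4 to 12 voxels.
#' @param seed optional integer seed.
#' @return a [sampling_grids()] of length `n`.
#' @export
sample_anchor_grids <- function(volume, n, size_range = c(4, 12), seed = NULL) {
  if (n <= 0) stop("n must be positive")
  shape <- dim(as_volume_array(volume))
  if (any(shape < 2)) stop("volume too small to sample grids")
  with_seed(seed, {
    centers <- cbind(floor(runif(n, 0, shape[1])),
                     floor(runif(n, 0, shape[2])),
                     floor(runif(n, 0, shape[3])))
    sizes <- runif(n, size_range[1], size_range[2])
    sampling_grids(centers, sizes)
  })
}

# uniform samples in a ball of radius r; n x 3 matrix
sample_ball <- function(n, r) {
  if (r <= 0) return(matrix(0, n, 3))
  dir <- matrix(rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  rad <- r * runif(n)^(1 / 3)
  dir * rad
}

# deformation matrices I + U(-e, e), n x 9 row-major
random_deformations <- function(n, e) {
  identity_rows(n) + matrix(runif(9 * n, -e, e), n, 9)
}

# compose per-grid transforms stored as n x 9 row-major: C = A %*% B per row
compose_rows <- function(A, B) {
  n <- nrow(A)
  out <- matrix(0, n, 9)
  for (i in 1:3) for (j in 1:3) {
    # C[i,j] = sum_k A[i,k] B[k,j]; row-major index (i-1)*3 + j
    out[, (i - 1) * 3 + j] <-
      A[, (i - 1) * 3 + 1] * B[, j] +
      A[, (i - 1) * 3 + 2] * B[, 3 + j] +
      A[, (i - 1) * 3 + 3] * B[, 6 + j]
  }
  out
}

#' Sample positive grids around an anchor
#'
#' Positive centers lie within a ball of radius `r_pos` around the anchor
#' center; each positive carries an independent random rotation and small
#' linear deformation, and its physical size is jittered relative to the
#' anchor's (clamped to `[4, 12]`).
#'
#' @param anchor a [sampling_grids()] of length 1 (or an index into one).
#' @param n_pos positives per anchor.
#' @param config an [augmentation_config()].
#' @param seed optional integer seed.
#' @return a [sampling_grids()] of length `n_pos`.
#' @export
sample_positive_grids <- function(anchor, n_pos, config = augmentation_config(),
                                  seed = NULL) {
  stopifnot(inherits(anchor, "vxr_grids"), length(anchor) == 1, n_pos >= 1)
  with_seed(seed, sample_positives_batch(anchor, n_pos, config))
}

# vectorized: for each of n anchors, n_pos positives; returns vxr_grids of
# length n * n_pos ordered positive-major within anchor (anchor 1's positives
# first)
sample_positives_batch <- function(anchors, n_pos, config) {
  n <- length(anchors)
  m <- n * n_pos
  rep_idx <- rep(seq_len(n), each = n_pos)
  centers <- anchors$centers[rep_idx, , drop = FALSE] + sample_ball(m, config$r_pos)
  sizes <- anchors$sizes[rep_idx] *
    runif(m, config$scale_jitter[1], config$scale_jitter[2])
  sizes <- pmin(pmax(sizes, 4), 12)
  R <- switch(config$rotation,
              none = identity_rows(m),
              axis90 = {
                g <- rot90_group()
                g[sample(nrow(g), m, replace = TRUE), , drop = FALSE]
              },
              uniform = random_rotations(m))
  A <- compose_rows(R, random_deformations(m, config$deform_range))
  sampling_grids(centers, sizes, A)
}

#' Extract a patch for one sampling grid
#'
#' Trilinear interpolation of the volume at the 16^3 transformed lattice
#' points spanning a cube of edge `a` centered at the grid center.
#' Out-of-bounds coordinates are reflected about the volume faces.
#'
#' @param volume a [vxr_volume] or 3D array.
#' @param grid a [sampling_grids()] of length 1.
#' @return a 16^3 array.
#' @export
extract_patch <- function(volume, grid) {
  stopifnot(inherits(grid, "vxr_grids"), length(grid) == 1)
  m <- extract_patches(as_volume_array(volume), grid$centers, grid$A, grid$sizes)
  array(m[, 1], c(16, 16, 16))
}

# vectorized extraction; patches as columns (4096 x n), voxel index
# z + 16*(y + 16*x), matching the (1,16,16,16,n) activation layout
extract_patches <- function(vol, centers, A, sizes, grid_points = 16L) {
  vol <- as_volume_array(vol)
  centers <- matrix(centers, ncol = 3)
  extract_patches_cpp(as.numeric(vol), dim(vol), centers, A,
                      rep_len(as.numeric(sizes), nrow(centers)),
                      as.integer(grid_points))
}

extract_patches_grids <- function(volume, grids) {
  extract_patches(as_volume_array(volume), grids$centers, grids$A, grids$sizes)
}

#' Photometric augmentation
#'
#' Applies, in order: an additive brightness shift, contrast scaling about the
#' patch mean, and additive Gaussian noise; the result is clipped to `[0, 1]`.
#'
#' @param patch a 16^3 array or a `4096 x n` matrix of patch columns.
#' @param config an [augmentation_config()].
#' @param seed optional integer seed.
#' @return transformed patch of the same shape.
#' @export
augment_photometric <- function(patch, config = augmentation_config(),
                                seed = NULL) {
  x <- if (is.matrix(patch)) patch else matrix(as.numeric(patch), ncol = 1)
  n <- ncol(x)
  with_seed(seed, {
    shift <- runif(n, config$brightness[1], config$brightness[2])
    scale <- runif(n, config$contrast[1], config$contrast[2])
    mu <- colMeans(x)
    x <- sweep(x, 2, mu, "-")
    x <- sweep(x, 2, scale, "*")
    x <- sweep(x, 2, mu + shift, "+")
    if (config$noise_sd > 0) {
      x <- x + matrix(rnorm(length(x), 0, config$noise_sd), nrow(x), n)
    }
    x <- clamp01(x)
  })
  if (is.matrix(patch)) x else array(x, dim(patch))
}

# random axis flips applied to patch columns (geometric augmentation)
augment_flips <- function(x, flip_prob, grid_points = 16L) {
  if (flip_prob <= 0) return(x)
  m <- grid_points
  idx <- array(seq_len(m^3), c(m, m, m))
  n <- ncol(x)
  do_flip <- matrix(runif(3 * n) < flip_prob, n, 3)
  for (i in seq_len(n)) {
    if (!any(do_flip[i, ])) next
    ix <- idx
    if (do_flip[i, 1]) ix <- ix[m:1, , , drop = FALSE]
    if (do_flip[i, 2]) ix <- ix[, m:1, , drop = FALSE]
    if (do_flip[i, 3]) ix <- ix[, , m:1, drop = FALSE]
    x[, i] <- x[as.vector(ix), i]
  }
  x
}

#' Dense per-voxel inference patches
#'
#' Yields, for every voxel of the volume, the 16^3 patch obtained by
#' trilinearly resampling the axis-aligned physical cube of edge `size`
#' (default 8, i.e. the 9^3 voxel support) centered on that voxel. Iteration
#' is row-major over chunks; chunking is transparent (any voxel's patch is
#' independent of the chunk shape). Borders use reflection padding.
#'
#' @param volume a [vxr_volume] or 3D array.
#' @param chunk integer 3-vector chunk shape; clamped to the volume shape.
#' @param size physical patch edge (default 8).
#' @return an iterator function; each call returns
#'   `list(coords = <n x 3 0-based voxel coordinates>, patches = <4096 x n>)`
#'   or `NULL` when exhausted.
#' @export
dense_inference_patches <- function(volume, chunk = c(16, 16, 16), size = 8) {
  vol <- as_volume_array(volume)
  shape <- dim(vol)
  chunk <- pmin(as.integer(chunk), shape)
  starts <- expand.grid(
    z = seq(0, shape[1] - 1, by = chunk[1]),
    y = seq(0, shape[2] - 1, by = chunk[2]),
    x = seq(0, shape[3] - 1, by = chunk[3])
  )
  # row-major order over chunks: x fastest varying last in expand.grid is fine
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > nrow(starts)) return(NULL)
    s <- as.integer(starts[i, ])
    ext <- pmin(chunk, shape - s)
    cz <- s[1] + seq_len(ext[1]) - 1
    cy <- s[2] + seq_len(ext[2]) - 1
    cx <- s[3] + seq_len(ext[3]) - 1
    coords <- as.matrix(expand.grid(z = cz, y = cy, x = cx))
    patches <- dense_patches_cpp(as.numeric(vol), dim(vol), coords, size, 16L)
    list(coords = coords, patches = patches)
  }
}
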