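test_that("anchor grids: count, size bounds, determinism", {
  vol <- array(runif(40^3), c(40, 40, 40))
  g <- sample_anchor_grids(vol, 128, seed = 1)
  expect_length(g, 128)
  expect_true(all(g$sizes >= 4 & g$sizes <= 12))
  expect_true(all(g$centers >= 0 & g$centers <= 39))
  expect_identical(g$A, voxelrep:::identity_rows(128))
  g8 <- sample_anchor_grids(vol, 16, size_range = c(8, 8), seed = 2)
  expect_true(all(g8$sizes == 8))
  expect_identical(sample_anchor_grids(vol, 32, seed = 7),
                   sample_anchor_grids(vol, 32, seed = 7))
  expect_error(sample_anchor_grids(vol, 0), "positive")
})

test_that("degenerate positive config reproduces the anchor grid", {
  anchor <- sampling_grids(matrix(c(10, 11, 12), 1), sizes = 6)
  cfg <- augmentation_config(rotation = "none", scale_jitter = c(1, 1),
                             r_pos = 0, deform_range = 0)
  pos <- sample_positive_grids(anchor, 3, cfg, seed = 1)
  expect_length(pos, 3)
  expect_true(all(abs(sweep(pos$centers, 2, anchor$centers[1, ])) == 0))
  expect_true(all(pos$sizes == 6))
  expect_equal(pos$A, voxelrep:::identity_rows(3))
})

test_that("positives: count and spherical neighbourhood statistics", {
  anchor <- sampling_grids(matrix(c(20, 20, 20), 1), sizes = 8)
  pos <- sample_positive_grids(anchor, 4, seed = 1)
  expect_length(pos, 4)
  set.seed(3)
  offs <- voxelrep:::sample_ball(1e4, 3)
  norms <- sqrt(rowSums(offs^2))
  expect_lte(max(norms), 3)
  # mean norm of uniform ball sampling = 3 * R / 4 = 2.25
  expect_equal(mean(norms), 2.25, tolerance = 0.02)
  # positive centers never farther than r_pos from the anchor
  cfg <- augmentation_config(r_pos = 2)
  set.seed(4)
  many <- voxelrep:::sample_positives_batch(
    sample_anchor_grids(array(0.5, c(40, 40, 40)), 2000, seed = 5), 4, cfg)
  d <- sqrt(rowSums((many$centers -
                       sample_anchor_grids(array(0.5, c(40, 40, 40)), 2000,
                                           seed = 5)$centers[
                         rep(1:2000, each = 4), ])^2))
  expect_lte(max(d), 2 + 1e-12)
})

test_that("positive sizes stay in the training bounds", {
  anchor <- sampling_grids(matrix(c(20, 20, 20), 1), sizes = 12)
  pos <- sample_positive_grids(anchor, 50, seed = 2)
  expect_true(all(pos$sizes >= 4 & pos$sizes <= 12))
})

test_that("lattice-aligned identity grid extracts the raw sub-volume", {
  set.seed(1)
  vol <- array(runif(24^3), c(24, 24, 24))
  g <- sampling_grids(matrix(c(7.5, 8.5, 7.5), 1), sizes = 15)
  p <- extract_patch(vol, g)
  expect_identical(dim(p), c(16L, 16L, 16L))
  expect_equal(p, vol[1:16, 2:17, 1:16], tolerance = 1e-12)
})

test_that("constant volumes give constant patches for any grid", {
  vol <- array(0.37, c(20, 20, 20))
  g <- sampling_grids(matrix(c(3.2, 17.9, 10.0), 1), sizes = 11,
                      A = random_rotations(1))
  expect_true(all(abs(extract_patch(vol, g) - 0.37) < 1e-12))
})

test_that("trilinear interpolation is exact on a linear ramp", {
  ramp <- array(rep(0:23, each = 24 * 24), c(24, 24, 24))   # f(z,y,x) = x
  g <- sampling_grids(matrix(c(11.2, 12.7, 12.1), 1), sizes = 8)
  p <- extract_patch(ramp, g)
  offs <- 8 * ((0:15) / 15 - 0.5)
  expected <- array(rep(12.1 + offs, each = 256), c(16, 16, 16))
  expect_lt(max(abs(p - expected)), 1e-6)
})

test_that("extraction matches the per-point trilinear oracle on random grids", {
  set.seed(11)
  for (trial in 1:5) {
    vol <- array(runif(24^3), c(24, 24, 24))
    g <- sampling_grids(matrix(runif(3, 2, 21), 1), sizes = runif(1, 4, 12),
                        A = voxelrep:::compose_rows(
                          random_rotations(1),
                          voxelrep:::random_deformations(1, 0.1)))
    p <- extract_patch(vol, g)
    coords <- oracle_grid_coords(g$centers[1, ], g$sizes[1], g$A[1, ])
    pts <- cbind(sample(1:16, 30, TRUE), sample(1:16, 30, TRUE),
                 sample(1:16, 30, TRUE))
    for (r in seq_len(nrow(pts))) {
      i <- pts[r, 1]; j <- pts[r, 2]; k <- pts[r, 3]
      expect_lt(abs(p[i, j, k] - oracle_trilinear(vol, coords[i, j, k, ])),
                1e-6)
    }
  }
})

test_that("dense fast path agrees with the general extractor", {
  set.seed(12)
  vol <- array(runif(20^3), c(20, 20, 20))
  ctr <- cbind(runif(50, -1, 20), runif(50, -1, 20), runif(50, -1, 20))
  a <- voxelrep:::dense_patches_cpp(as.numeric(vol), dim(vol), ctr, 8, 16L)
  b <- voxelrep:::extract_patches(vol, ctr, voxelrep:::identity_rows(50),
                                  rep(8, 50))
  expect_lt(max(abs(a - b)), 1e-12)
})

test_that("photometric augmentation: identity, brightness, contrast", {
  p <- array(0.5, c(16, 16, 16))
  idcfg <- augmentation_config(brightness = c(0, 0), contrast = c(1, 1),
                               noise_sd = 0)
  expect_equal(augment_photometric(p, idcfg), p)
  bcfg <- augmentation_config(brightness = c(0.1, 0.1), contrast = c(1, 1),
                              noise_sd = 0)
  expect_true(all(abs(augment_photometric(p, bcfg) - 0.6) < 1e-12))
  q <- array(rep(c(0.4, 0.6), each = 2048), c(16, 16, 16))
  ccfg <- augmentation_config(brightness = c(0, 0), contrast = c(2, 2),
                              noise_sd = 0)
  out <- augment_photometric(q, ccfg)
  expect_equal(sort(unique(as.vector(out))), c(0.3, 0.7))
  # clipping keeps outputs in [0, 1]
  noisy <- augment_photometric(array(runif(16^3), c(16, 16, 16)),
                               augmentation_config(noise_sd = 0.5), seed = 1)
  expect_true(all(noisy >= 0 & noisy <= 1))
})

test_that("dense inference yields one patch per voxel, chunk-independently", {
  vol <- array(runif(4^3), c(4, 4, 4))
  it <- dense_inference_patches(vol, chunk = c(4, 4, 4))
  ch <- it()
  expect_identical(dim(ch$patches), c(4096L, 64L))
  expect_null(it())
  # chunking is transparent and covers every voxel exactly once
  it2 <- dense_inference_patches(vol, chunk = c(3, 2, 4))
  seen <- NULL
  agree <- TRUE
  while (!is.null(c2 <- it2())) {
    key <- c2$coords[, 1] + 4 * (c2$coords[, 2] + 4 * c2$coords[, 3])
    seen <- c(seen, key)
    ref_cols <- match(key, ch$coords[, 1] + 4 * (ch$coords[, 2] + 4 * ch$coords[, 3]))
    agree <- agree && max(abs(c2$patches - ch$patches[, ref_cols])) == 0
  }
  expect_true(agree)
  expect_equal(sort(seen), 0:63)
})

test_that("inference patch sample spacing is size/15 along each axis", {
  ramp <- array(rep(0:31, each = 32 * 32), c(32, 32, 32))  # f = x
  it <- dense_inference_patches(ramp, chunk = c(1, 1, 1))
  # advance to the center voxel (16, 16, 16) 0-based
  repeat {
    ch <- it()
    if (all(ch$coords[1, ] == c(16, 16, 16))) break
  }
  p <- array(ch$patches[, 1], c(16, 16, 16))
  along_x <- p[8, 8, ]
  expect_equal(diff(along_x), rep(8 / 15, 15), tolerance = 1e-9)
})
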