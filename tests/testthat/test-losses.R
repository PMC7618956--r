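test_that("reconstruction loss: perfect fit, hand value, batch normalization", {
  x <- matrix(runif(4096 * 3), 4096)
  expect_equal(reconstruction_loss(x, x, size = 8), 0)
  # b = 1, a = 2, every residual entry c: 16^3 * c^2 / 8
  c0 <- 0.03
  x1 <- matrix(0.5, 4096, 1)
  expect_equal(reconstruction_loss(x1, x1 - c0, size = 2, n_anchors = 1),
               4096 * c0^2 / 8)
  # duplicating every sample while doubling b leaves the loss unchanged
  mu <- matrix(runif(4096 * 3), 4096)
  a <- runif(3, 4, 12)
  l1 <- reconstruction_loss(x, mu, a, n_anchors = 3)
  l2 <- reconstruction_loss(cbind(x, x), cbind(mu, mu), c(a, a), n_anchors = 6)
  expect_equal(l1, l2)
  expect_error(reconstruction_loss(x, mu[, 1:2], a), "mismatch")
})

test_that("KL loss: closed form, duplication invariance, errors", {
  expect_identical(kl_loss(matrix(0, 4, 6), matrix(1, 4, 6)), 0)
  expect_equal(kl_loss(matrix(1, 1, 1), matrix(1, 1, 1), n_anchors = 1, d = 1),
               0.5, tolerance = 1e-12)
  mu <- matrix(rnorm(8), 2); sg <- matrix(runif(8, 0.5, 2), 2)
  expect_equal(kl_loss(mu, sg, n_anchors = 4, d = 2),
               kl_loss(cbind(mu, mu), cbind(sg, sg), n_anchors = 8, d = 2))
  expect_gte(kl_loss(mu, sg), 0)
  expect_gte(kl_loss(mu, sg, reversed = TRUE), 0)
  expect_equal(kl_loss(matrix(0, 2, 2), matrix(1, 2, 2), reversed = TRUE), 0)
  expect_error(kl_loss(mu, sg * 0), "positive")
})

test_that("similarity tensor: extremes, symmetry, zero convention, oracle", {
  # all identical embeddings
  emb <- array(1, c(2, 2, 3))
  expect_true(all(abs(similarity_tensor(emb) - 1) < 1e-12))
  # orthogonal and antiparallel pairs
  emb2 <- array(0, c(1, 3, 2))
  emb2[1, 1, ] <- c(1, 0)
  emb2[1, 2, ] <- c(0, 1)
  emb2[1, 3, ] <- c(-1, 0)
  S <- similarity_tensor(emb2)
  expect_equal(S[1, 1, 1, 2], 0)
  expect_equal(S[1, 1, 1, 3], -1)
  expect_equal(S[1, 1, 1, 1], 1)
  # zero vector has similarity 0
  emb3 <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  emb3[1, 1, ] <- 0
  S3 <- similarity_tensor(emb3)
  expect_true(all(S3[1, 1, 2, ] == 0))
  # random embeddings match the loop oracle
  set.seed(8)
  emb4 <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  expect_equal(similarity_tensor(emb4), oracle_similarity_tensor(emb4),
               tolerance = 1e-6)
  # symmetry under (j,i) <-> (k,l)
  S4 <- similarity_tensor(emb4)
  expect_equal(S4, aperm(S4, c(3, 4, 1, 2)), tolerance = 1e-12)
})

test_that("multi-similarity loss at the margin equals the hand value", {
  # b = 2, n_pos = 1, every similarity equal to the margin
  lc <- loss_config(alpha = 2, beta = 50, lambda = 0.4)
  S <- array(lc$lambda, c(2, 2, 2, 2))
  got <- multi_similarity_loss(S, lc)
  expect_equal(got, log(2) / lc$alpha + log(3) / lc$beta, tolerance = 1e-12)
  # ideal similarities give a strictly smaller loss
  emb <- array(0, c(2, 2, 2))
  emb[, 1, ] <- matrix(c(1, 0), 2, 2, byrow = TRUE)   # sample 1 -> +x
  emb[, 2, ] <- matrix(c(-1, 0), 2, 2, byrow = TRUE)  # sample 2 -> -x
  lc2 <- loss_config(alpha = 2, beta = 2, lambda = 0.5)
  S_ideal <- similarity_tensor(emb)
  S_flat <- array(lc2$lambda, c(2, 2, 2, 2))
  expect_lt(multi_similarity_loss(S_ideal, lc2),
            multi_similarity_loss(S_flat, lc2))
  expect_error(multi_similarity_loss(array(1, c(2, 1, 2, 1)), lc), "2 samples")
})

test_that("multi-similarity loss matches the quadruple-loop oracle", {
  set.seed(9)
  for (trial in 1:20) {
    b <- sample(2:4, 1)
    r <- 1 + sample(1:2, 1)
    dms <- sample(2:4, 1)
    emb <- array(rnorm(r * b * dms), c(r, b, dms))
    S <- similarity_tensor(emb)
    lc <- loss_config(alpha = runif(1, 0.5, 3), beta = runif(1, 1, 10),
                      lambda = runif(1, 0, 1))
    expect_equal(multi_similarity_loss(S, lc),
                 oracle_ms_loss(S, lc$alpha, lc$beta, lc$lambda),
                 tolerance = 1e-6)
  }
})

test_that("ms loss falls when positives tighten and rises when negatives do", {
  set.seed(10)
  emb <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  S <- similarity_tensor(emb)
  lc <- loss_config(alpha = 2, beta = 5, lambda = 0.5)
  l0 <- multi_similarity_loss(S, lc)
  h <- 1e-4
  # increase a within-sample similarity (both ordered entries)
  Sp <- S; Sp[1, 2, 3, 2] <- Sp[1, 2, 3, 2] + h; Sp[3, 2, 1, 2] <- Sp[3, 2, 1, 2] + h
  expect_lt(multi_similarity_loss(Sp, lc), l0)
  # increase a cross-sample similarity
  Sn <- S; Sn[1, 1, 2, 3] <- Sn[1, 1, 2, 3] + h; Sn[2, 3, 1, 1] <- Sn[2, 3, 1, 1] + h
  expect_gt(multi_similarity_loss(Sn, lc), l0)
})

test_that("training fast path agrees with the tensor API and its gradient", {
  set.seed(11)
  b <- 3; r <- 3; dms <- 4
  E <- matrix(rnorm(dms * r * b), dms)     # columns (j, i), j fastest
  lc <- loss_config(alpha = 2, beta = 8, lambda = 0.7)
  fast <- voxelrep:::ms_loss_grad(E, r, b, lc$alpha, lc$beta, lc$lambda)
  emb <- array(t(E), c(r, b, dms))
  expect_equal(fast$loss, multi_similarity_loss(similarity_tensor(emb), lc),
               tolerance = 1e-10)
  # numeric gradient
  h <- 1e-6
  for (idx in sample(length(E), 6)) {
    Ep <- E; Ep[idx] <- Ep[idx] + h
    Em <- E; Em[idx] <- Em[idx] - h
    num <- (voxelrep:::ms_loss_grad(Ep, r, b, lc$alpha, lc$beta, lc$lambda)$loss -
              voxelrep:::ms_loss_grad(Em, r, b, lc$alpha, lc$beta, lc$lambda)$loss) / (2 * h)
    expect_equal(fast$dE[idx], num, tolerance = 1e-4)
  }
})

test_that("reconstruction and KL agree with loop oracles on random batches", {
  set.seed(12)
  for (trial in 1:20) {
    b <- sample(2:4, 1)
    n <- b * (1 + sample(1:2, 1))
    d <- sample(2:4, 1)
    x <- matrix(runif(4096 * n), 4096)
    mu_x <- matrix(runif(4096 * n), 4096)
    sizes <- runif(n, 4, 12)
    expect_equal(reconstruction_loss(x, mu_x, sizes, n_anchors = b),
                 oracle_recon_loss(x, mu_x, sizes, b), tolerance = 1e-6)
    mu <- matrix(rnorm(d * n), d)
    sg <- matrix(runif(d * n, 0.3, 2.5), d)
    expect_equal(kl_loss(mu, sg, n_anchors = b, d = d),
                 oracle_kl_loss(mu, sg, b, d), tolerance = 1e-6)
  }
})

test_that("batch loss is the stated weighted sum", {
  lc <- loss_config(theta_kl = 0.5, theta_ms = 2)
  expect_equal(batch_loss(1, 1, 1, lc), 3.5)
  lc0 <- loss_config(theta_kl = 0, theta_ms = 0)
  expect_equal(batch_loss(0.42, 99, 99, lc0), 0.42)
  expect_error(batch_loss(NaN, 0, 0, lc), "finite")
})
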