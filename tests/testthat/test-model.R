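test_that("encode satisfies the shape contract and is deterministic", {
  m <- tiny_vae(latent_dim = 8, semantic_dim = 4)
  x <- matrix(runif(4096 * 5), 4096)
  code <- encode(m, x)
  expect_identical(dim(code$mu), c(8L, 5L))
  expect_identical(dim(code$sigma), c(8L, 5L))
  expect_true(all(code$sigma > 0))
  expect_true(all(is.finite(code$mu)) && all(is.finite(code$sigma)))
  # identical inputs give identical codes; repeat calls agree
  x2 <- x[, c(1, 1, 1)]
  c2 <- encode(m, x2)
  expect_equal(c2$mu[, 1], c2$mu[, 2])
  expect_identical(encode(m, x)$mu, code$mu)
  expect_error(encode(m, matrix(runif(100), 10)), "16")
})

test_that("encode is permutation-equivariant over the batch", {
  m <- tiny_vae()
  x <- matrix(runif(4096 * 6), 4096)
  perm <- c(4, 1, 6, 2, 5, 3)
  a <- encode(m, x)$mu[, perm]
  b <- encode(m, x[, perm])$mu
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("reparameterization has the right moments and determinism", {
  code <- list(mu = matrix(1.5, 1, 1e5), sigma = matrix(0.7, 1, 1e5))
  z <- reparameterize(code, seed = 1)
  se <- 0.7 / sqrt(1e5)
  expect_lt(abs(mean(z) - 1.5), 3 * se)
  expect_equal(sd(z), 0.7, tolerance = 0.01)
  expect_identical(z, reparameterize(code, seed = 1))
  # sigma -> 0 limit collapses to the mean
  tight <- list(mu = matrix(2, 4, 3), sigma = matrix(1e-12, 4, 3))
  expect_equal(reparameterize(tight, seed = 2), tight$mu, tolerance = 1e-9)
})

test_that("decode satisfies shape and range contracts", {
  m <- tiny_vae(latent_dim = 8)
  z <- matrix(rnorm(8 * 7), 8)
  y <- decode(m, z)
  expect_identical(dim(y), c(4096L, 7L))
  expect_true(all(y > 0 & y < 1))
  expect_error(decode(m, matrix(rnorm(5 * 2), 5)), "dimension")
})

test_that("analytic gradients match finite differences", {
  set.seed(1)
  cfg <- vae_config(latent_dim = 6, semantic_dim = 3,
                    encoder_channels = c(2, 3, 4, 5))
  m <- vae_init(cfg, seed = 2)
  # linear activations make the loss C2 in the parameters, so central
  # differences are exact to truncation error; LeakyReLU kinks would
  # otherwise contaminate bias gradients (a bias shifts thousands of
  # pre-activations, some of which always sit within h of a kink)
  m$config$lrelu_slope <- 1
  b <- 2; r <- 2
  x <- matrix(runif(4096 * b * r), 4096)
  xT <- t(x)
  sizes <- runif(b * r, 4, 12)
  lc <- loss_config(theta_kl = 0.3, theta_ms = 0.7)
  eps <- matrix(rnorm(6 * b * r), 6)
  fwd <- function(model) {
    enc <- voxelrep:::vae_enc_forward(model, xT, keep_cache = TRUE)
    z <- enc$mu + enc$sigma * eps
    dec <- voxelrep:::vae_dec_forward(model, z, keep_cache = TRUE)
    recon <- reconstruction_loss(x, t(dec$mu_x), sizes, n_anchors = b)
    kl <- kl_loss(enc$mu, enc$sigma, n_anchors = b, d = cfg$latent_dim)
    msr <- voxelrep:::ms_loss_grad(enc$mu[1:3, , drop = FALSE], r, b,
                                   lc$alpha, lc$beta, lc$lambda)
    list(total = batch_loss(recon, kl, msr$loss, lc), enc = enc, dec = dec,
         msr = msr)
  }
  f0 <- fwd(m)
  d_mu_x <- sweep(f0$dec$mu_x - xT, 1, sizes^3, "/") * (2 / b)
  d_mu <- lc$theta_kl * f0$enc$mu / (b * cfg$latent_dim)
  d_lv <- lc$theta_kl * 0.5 * (f0$enc$sigma^2 - 1) / (b * cfg$latent_dim)
  d_mu[1:3, ] <- d_mu[1:3, , drop = FALSE] + lc$theta_ms * f0$msr$dE
  gr <- voxelrep:::vae_backward(m, x, f0$enc, f0$dec, d_mu_x, d_mu, d_lv, eps)
  set.seed(99)
  relerr <- c()
  nonzero <- c()
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), 1)
    h <- 1e-6      # small enough that LeakyReLU kink crossings are rare
    mp <- m; mp$params[[nm]][idx] <- mp$params[[nm]][idx] + h
    mm <- m; mm$params[[nm]][idx] <- mm$params[[nm]][idx] - h
    num <- (fwd(mp)$total - fwd(mm)$total) / (2 * h)
    ana <- gr[[nm]][idx]
    # relative where the gradient is appreciable, absolute (1e-6 scale)
    # where it vanishes and central differences are all roundoff
    relerr <- c(relerr, abs(num - ana) / max(abs(num), abs(ana), 1e-6))
    nonzero <- c(nonzero, any(gr[[nm]] != 0))
  }
  expect_lt(max(relerr), 1e-4)
  # every parameter tensor receives gradient signal
  expect_true(all(nonzero))
  # with the real (kinked) activation the backward pass stays finite
  m2 <- vae_init(cfg, seed = 2)
  f2 <- fwd(m2)
  dmx2 <- sweep(f2$dec$mu_x - xT, 1, sizes^3, "/") * (2 / b)
  dmu2 <- lc$theta_kl * f2$enc$mu / (b * cfg$latent_dim)
  dlv2 <- lc$theta_kl * 0.5 * (f2$enc$sigma^2 - 1) / (b * cfg$latent_dim)
  dmu2[1:3, ] <- dmu2[1:3, , drop = FALSE] + lc$theta_ms * f2$msr$dE
  g2 <- voxelrep:::vae_backward(m2, x, f2$enc, f2$dec, dmx2, dmu2, dlv2, eps)
  expect_true(all(is.finite(unlist(g2))))
})

test_that("each loss term propagates gradient into the encoder", {
  set.seed(2)
  cfg <- vae_config(latent_dim = 6, semantic_dim = 3,
                    encoder_channels = c(2, 3, 4, 5))
  m <- vae_init(cfg, seed = 3)
  b <- 2; r <- 2
  x <- matrix(runif(4096 * b * r), 4096)
  enc <- voxelrep:::vae_enc_forward(m, t(x), keep_cache = TRUE)
  eps <- matrix(rnorm(6 * b * r), 6)
  z <- enc$mu + enc$sigma * eps
  dec <- voxelrep:::vae_dec_forward(m, z, keep_cache = TRUE)
  zero_mu <- enc$mu * 0
  # reconstruction-only gradient
  g_rec <- voxelrep:::vae_backward(m, x, enc, dec,
                                   (dec$mu_x - t(x)) * 2 / b, zero_mu,
                                   zero_mu, eps)
  expect_gt(max(abs(g_rec$encW1)), 0)
  # KL-only gradient
  g_kl <- voxelrep:::vae_backward(m, x, enc, NULL, NULL,
                                  enc$mu / b, 0.5 * (enc$sigma^2 - 1) / b,
                                  NULL)
  expect_gt(max(abs(g_kl$encW1)), 0)
  # metric-only gradient (semantic dims)
  msr <- voxelrep:::ms_loss_grad(enc$mu[1:3, , drop = FALSE], r, b, 2, 50, 1)
  d_mu <- zero_mu; d_mu[1:3, ] <- msr$dE
  g_ms <- voxelrep:::vae_backward(m, x, enc, NULL, NULL, d_mu, zero_mu, NULL)
  expect_gt(max(abs(g_ms$encW1)), 0)
})

test_that("the VAE can overfit a single patch to low reconstruction error", {
  set.seed(5)
  cfg <- vae_config(latent_dim = 8, semantic_dim = 4,
                    encoder_channels = c(4, 8, 16, 32))
  m <- vae_init(cfg, seed = 1)
  ph <- generate_phantom(one_region_spec(noise_sd = 0.02, kind = "stripes"))
  x <- voxelrep:::extract_patches(
    ph$volume$data, matrix(c(16, 16, 16), 1),
    voxelrep:::identity_rows(1), 8)
  xT <- t(x)
  opt <- voxelrep:::adam_init(m$params)
  for (it in 1:250) {
    enc <- voxelrep:::vae_enc_forward(m, xT, keep_cache = TRUE)
    dec <- voxelrep:::vae_dec_forward(m, enc$mu, keep_cache = TRUE)  # z = mu
    d_mu_x <- (dec$mu_x - xT) * 2
    gr <- voxelrep:::vae_backward(m, x, enc, dec, d_mu_x, enc$mu * 0,
                                  enc$mu * 0, enc$mu * 0)
    upd <- voxelrep:::adam_step(m$params, gr, opt, 3e-3, 0.9, 0.999, 1e-8)
    m$params <- upd$params
    opt <- upd$state
  }
  enc <- encode(m, x)
  rec <- decode(m, enc$mu)
  expect_lt(mean((rec - x)^2), 1e-2)
})

test_that("checkpoints round-trip the model", {
  m <- tiny_vae(seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  x <- matrix(runif(4096 * 2), 4096)
  expect_identical(encode(m, x)$mu, encode(m2, x)$mu)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
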