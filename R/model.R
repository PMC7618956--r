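#' VAE configuration
#'
#' Architecture of the 3D convolutional variational autoencoder mapping 16^3
#' patches to a `latent_dim`-dimensional Gaussian latent and back. The first
#' `semantic_dim` latent dimensions are the semantic subspace: the only
#' dimensions receiving the metric-learning signal and the only ones used for
#' clustering. The encoder is four stride-2 conv blocks (kernel 4, LeakyReLU)
#' reducing 16^3 to 1^3, followed by affine heads for the latent mean and
#' log-variance; the decoder mirrors it with transposed convolutions and a
#' sigmoid output so reconstructions stay in `[0, 1]`.
#'
#' @param latent_dim total latent dimension `d` (default 64).
#' @param semantic_dim semantic subspace dimension `d_MS` (default 8),
#'   `0 < semantic_dim <= latent_dim`.
#' @param encoder_channels four conv channel counts (default 16, 32, 64, 128).
#' @param kernel conv kernel size, 2 (non-overlapping, the default; an order
#'   of magnitude cheaper on CPU with comparable texture discrimination at
#'   this patch size) or 4 (overlapping).
#' @param logvar_init initial bias of the log-variance head. The default -3
#'   starts the posterior narrow (`sigma ~ 0.22`) so early reconstruction
#'   gradients are not swamped by reparameterization noise; the KL term
#'   re-widens it as training proceeds.
#' @param patch_points lattice points per axis; fixed at 16.
#' @return a `vxr_vae_config`.
#' @export
vae_config <- function(latent_dim = 64, semantic_dim = 8,
                       encoder_channels = c(16, 32, 64, 128),
                       kernel = 2, logvar_init = -3, patch_points = 16) {
  stopifnot(semantic_dim > 0, semantic_dim <= latent_dim,
            length(encoder_channels) == 4, all(encoder_channels >= 1),
            kernel %in% c(2, 4), patch_points == 16)
  structure(list(latent_dim = as.integer(latent_dim),
                 semantic_dim = as.integer(semantic_dim),
                 encoder_channels = as.integer(encoder_channels),
                 patch_points = 16L, kernel = as.integer(kernel), stride = 2L,
                 pad = as.integer((kernel - 2) / 2),
                 lrelu_slope = 0.1, logvar_init = logvar_init,
                 logvar_min = 2 * log(1e-4), logvar_max = 2 * log(10)),
            class = "vxr_vae_config")
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(runif(nrow * ncol, -sqrt(6 / fan_in), sqrt(6 / fan_in)), nrow, ncol)
}

#' Initialize a VAE model
#'
#' @param config a [vae_config()].
#' @param seed integer seed for weight initialization.
#' @return a `vxr_vae` model (list of `config` and `params`).
#' @export
vae_init <- function(config = vae_config(), seed = 1) {
  ch <- c(1L, config$encoder_channels)
  k3 <- config$kernel^3
  d <- config$latent_dim
  with_seed(seed, {
    params <- list()
    for (i in 1:4) {
      fan <- ch[i] * k3
      params[[paste0("encW", i)]] <- he_init(ch[i + 1], ch[i] * k3, fan)
      params[[paste0("encb", i)]] <- numeric(ch[i + 1])
    }
    c4 <- ch[5]
    params$Wmu <- he_init(d, c4, c4)
    params$bmu <- numeric(d)
    params$Wlv <- he_init(d, c4, c4) * 0.1
    params$blv <- rep(config$logvar_init %||% 0, d)
    params$Wd <- he_init(c4, d, d)
    params$bd <- numeric(c4)
    for (i in 4:1) {
      # tconv mapping ch[i+1] -> ch[i]; weight Cin x (Cout*k^3)
      fan <- ch[i + 1] * k3
      params[[paste0("decW", i)]] <- he_init(ch[i + 1], ch[i] * k3, fan)
      params[[paste0("decb", i)]] <- numeric(ch[i])
    }
    structure(list(config = config, params = params), class = "vxr_vae")
  })
}

#' @export
print.vxr_vae <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<vxr_vae d=%d (semantic %d), channels %s, %d parameters>\n",
              cfg$latent_dim, cfg$semantic_dim,
              paste(cfg$encoder_channels, collapse = "-"), np))
  invisible(x)
}

as_patch_matrix <- function(x, patch_points = 16L) {
  v <- patch_points^3
  if (is.matrix(x)) {
    if (nrow(x) != v) stop("patches must be ", patch_points, "^3; got ", nrow(x), " voxels")
    return(x)
  }
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3, 4)) || any(d[1:3] != patch_points)) {
    stop("patches must be ", patch_points, "^3 arrays or a ",
         v, " x n matrix")
  }
  matrix(as.numeric(x), v)
}

# encoder forward; xT: N x 4096 matrix (sample-major activations).
# Returns mu, logvar, sigma as d x N (+ caches).
vae_enc_forward <- function(model, xT, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  ch <- c(1L, cfg$encoder_channels)
  sz <- c(16L, 8L, 4L, 2L, 1L)
  h <- xT
  cache <- if (keep_cache) list(inputs = list(), pre = list()) else NULL
  for (i in 1:4) {
    if (keep_cache) cache$inputs[[i]] <- h
    pre <- conv3d_fwd_cpp(h, p[[paste0("encW", i)]], p[[paste0("encb", i)]],
                          ch[i], sz[i], cfg$kernel, cfg$stride, cfg$pad)
    if (keep_cache) cache$pre[[i]] <- pre
    h <- lrelu(pre, cfg$lrelu_slope)
  }
  mu <- tcrossprod(p$Wmu, h) + p$bmu          # d x N
  lv_raw <- tcrossprod(p$Wlv, h) + p$blv
  lv <- pmin(pmax(lv_raw, cfg$logvar_min), cfg$logvar_max)
  if (keep_cache) {
    cache$h4 <- h
    cache$lv_raw <- lv_raw
  }
  list(mu = mu, logvar = lv, sigma = exp(lv / 2), cache = cache)
}

# decoder forward; z: d x N. Returns mu_x (N x 4096 in (0,1)) (+ caches).
vae_dec_forward <- function(model, z, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  ch <- c(1L, cfg$encoder_channels)
  sz <- c(1L, 2L, 4L, 8L)   # input spatial size of tconv layer i = 4..1
  g_pre <- t(p$Wd %*% z + p$bd)               # N x C4
  g <- lrelu(g_pre, cfg$lrelu_slope)
  cache <- if (keep_cache) list(inputs = list(), pre = list(),
                                g_pre = g_pre, z = z) else NULL
  h <- g
  for (i in 4:1) {
    if (keep_cache) cache$inputs[[i]] <- h
    pre <- tconv3d_fwd_cpp(h, p[[paste0("decW", i)]], p[[paste0("decb", i)]],
                           ch[i + 1], sz[5 - i], cfg$kernel, cfg$stride, cfg$pad)
    if (i > 1) {
      if (keep_cache) cache$pre[[i]] <- pre
      h <- lrelu(pre, cfg$lrelu_slope)
    } else {
      if (keep_cache) cache$out_pre <- pre
      h <- sigmoid(pre)
    }
  }
  list(mu_x = h, cache = cache)
}

#' Encode patches to latent Gaussian parameters
#'
#' Deterministic forward pass of the encoder.
#'
#' @param model a `vxr_vae`.
#' @param x patches: a 16^3 array, a `(16,16,16,n)` array, or a `4096 x n`
#'   matrix of patch columns, intensities in `[0, 1]`.
#' @return list with `mu` and `sigma`, each `d x n`, and `logvar`.
#' @export
encode <- function(model, x) {
  out <- vae_enc_forward(model, t(as_patch_matrix(x, model$config$patch_points)))
  out[c("mu", "sigma", "logvar")]
}

#' Reparameterization draw
#'
#' `z = mu + sigma * eps`, `eps ~ N(0, I)`.
#'
#' @param code list with `mu` and `sigma` (`d x n`).
#' @param seed optional integer seed.
#' @return `d x n` matrix of latent samples.
#' @export
reparameterize <- function(code, seed = NULL) {
  with_seed(seed, {
    code$mu + code$sigma * matrix(rnorm(length(code$mu)),
                                  nrow(code$mu), ncol(code$mu))
  })
}

#' Decode latent vectors to reconstructed patches
#'
#' @param model a `vxr_vae`.
#' @param z `d x n` matrix (or length-`d` vector) of latent codes.
#' @return `4096 x n` matrix of reconstructions in `(0, 1)`.
#' @export
decode <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  if (nrow(z) != model$config$latent_dim) {
    stop("latent dimension mismatch: model expects ", model$config$latent_dim,
         ", got ", nrow(z))
  }
  t(vae_dec_forward(model, z)$mu_x)
}

# full backward pass. Arguments:
#   enc, dec: forward outputs with caches
#   d_mu_x: gradient w.r.t. mu_x (N x 4096, sample-major)
#   d_mu:   gradient w.r.t. mu from KL + MS terms (d x N)
#   d_lv:   gradient w.r.t. (clamped) logvar from KL (d x N)
#   eps:    the reparameterization noise (d x N), or NULL if decoder unused
# Returns named list of gradients matching model$params.
vae_backward <- function(model, x, enc, dec, d_mu_x, d_mu, d_lv, eps) {
  cfg <- model$config
  p <- model$params
  ch <- c(1L, cfg$encoder_channels)
  sz_enc <- c(16L, 8L, 4L, 2L)       # input size of enc layer i
  sz_dec <- c(1L, 2L, 4L, 8L)        # input size of dec layer i = 4..1
  grads <- list()

  if (!is.null(dec)) {
    # through sigmoid output
    s <- dec$mu_x
    dh <- d_mu_x * s * (1 - s)
    for (i in 1:4) {
      if (i > 1) dh <- dh * lrelu_grad(dec$cache$pre[[i]], cfg$lrelu_slope)
      bw <- tconv3d_bwd_cpp(dec$cache$inputs[[i]], p[[paste0("decW", i)]], dh,
                            ch[i + 1], sz_dec[5 - i], cfg$kernel, cfg$stride,
                            cfg$pad)
      grads[[paste0("decW", i)]] <- bw$dW
      grads[[paste0("decb", i)]] <- as.numeric(bw$db)
      dh <- bw$dx
    }
    dg_pre <- dh * lrelu_grad(dec$cache$g_pre, cfg$lrelu_slope)  # N x C4
    grads$Wd <- crossprod(dg_pre, t(dec$cache$z))                # C4 x d
    grads$bd <- colSums(dg_pre)
    dz <- crossprod(p$Wd, t(dg_pre))                             # d x N
    # z = mu + exp(lv/2) * eps
    d_mu <- d_mu + dz
    d_lv <- d_lv + dz * eps * exp(enc$logvar / 2) / 2
  } else {
    grads$Wd <- p$Wd * 0; grads$bd <- p$bd * 0
    for (i in 1:4) {
      grads[[paste0("decW", i)]] <- p[[paste0("decW", i)]] * 0
      grads[[paste0("decb", i)]] <- p[[paste0("decb", i)]] * 0
    }
  }

  # clamp on logvar: zero gradient where saturated
  lvr <- enc$cache$lv_raw
  d_lv <- d_lv * (lvr > cfg$logvar_min & lvr < cfg$logvar_max)

  h4 <- enc$cache$h4                          # N x C4
  grads$Wmu <- d_mu %*% h4                    # d x C4
  grads$bmu <- rowSums(d_mu)
  grads$Wlv <- d_lv %*% h4
  grads$blv <- rowSums(d_lv)
  dh <- crossprod(d_mu, p$Wmu) + crossprod(d_lv, p$Wlv)   # N x C4
  for (i in 4:1) {
    dh <- dh * lrelu_grad(enc$cache$pre[[i]], cfg$lrelu_slope)
    bw <- conv3d_bwd_cpp(enc$cache$inputs[[i]], p[[paste0("encW", i)]], dh,
                         ch[i], sz_enc[i], cfg$kernel, cfg$stride, cfg$pad,
                         need_dx = (i > 1))   # input gradient is never used
    grads[[paste0("encW", i)]] <- bw$dW
    grads[[paste0("encb", i)]] <- as.numeric(bw$db)
    dh <- bw$dx
  }
  grads
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the [vae_config()] and an optional provenance hash of
#' the training configuration.
#'
#' @param model a `vxr_vae`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` invisibly for save; the model for load.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "vxr_vae")) stop("not a vxr_vae checkpoint: ", path)
  model
}
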