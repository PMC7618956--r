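#' Training configuration
#'
#' Assembles sampling, model, loss and optimizer settings for [train()]. The
#' training budget is expressed in anchors: `anchors_per_stack` anchors are
#' drawn per training volume (the published experiments used millions per
#' stack; the desk-scale default of 20,000 trains a small model on a phantom
#' in minutes on one CPU).
#'
#' @param anchors_per_stack anchor budget per volume (>= `batch_anchors`).
#' @param batch_anchors anchors per batch `b` (default 128).
#' @param n_pos positives per anchor (default 4).
#' @param size_range training physical-size range (default `c(4, 12)`).
#' @param vae a [vae_config()].
#' @param loss a [loss_config()].
#' @param augment an [augmentation_config()].
#' @param seed master seed; all training randomness derives from it.
#' @param lr Adam learning rate.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @return a `vxr_train_config`.
#' @export
train_config <- function(anchors_per_stack = 20000, batch_anchors = 128,
                         n_pos = 4, size_range = c(4, 12),
                         vae = vae_config(), loss = loss_config(),
                         augment = augmentation_config(), seed = 1,
                         lr = 3e-3, adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  stopifnot(anchors_per_stack >= batch_anchors, batch_anchors >= 2, n_pos >= 1)
  structure(list(anchors_per_stack = anchors_per_stack,
                 batch_anchors = as.integer(batch_anchors),
                 n_pos = as.integer(n_pos), size_range = size_range,
                 vae = vae, loss = loss, augment = augment,
                 seed = as.integer(seed), lr = lr, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps),
            class = "vxr_train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1, b2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# one training batch: sample -> extract -> augment -> forward -> loss+grads.
# Returns list(loss components, grads, n_anchors).
train_batch <- function(model, volumes, vol_idx, config) {
  cfg <- config
  b <- cfg$batch_anchors
  P <- cfg$n_pos
  r <- 1L + P
  d <- cfg$vae$latent_dim
  dms <- cfg$vae$semantic_dim

  # per-volume anchor allocation (round-robin across volumes)
  xs <- vector("list", length(volumes))
  sizes_all <- matrix(0, r, b)
  x <- matrix(0, cfg$vae$patch_points^3, r * b)
  col0 <- 0L
  for (v in seq_along(volumes)) {
    nv <- sum(vol_idx == v)
    if (nv == 0) next
    anchors <- sample_anchor_grids(volumes[[v]], nv, cfg$size_range)
    positives <- sample_positives_batch(anchors, P, cfg$augment)
    va <- as_volume_array(volumes[[v]])
    pa <- extract_patches_grids(va, anchors)        # 4096 x nv
    pp <- extract_patches_grids(va, positives)      # 4096 x nv*P
    for (ii in seq_len(nv)) {
      cols <- col0 + (ii - 1L) * r
      x[, cols + 1L] <- pa[, ii]
      x[, cols + 1L + seq_len(P)] <- pp[, (ii - 1L) * P + seq_len(P)]
      sizes_all[1, col0 / r + ii] <- anchors$sizes[ii]
      sizes_all[1 + seq_len(P), col0 / r + ii] <-
        positives$sizes[(ii - 1L) * P + seq_len(P)]
    }
    col0 <- col0 + nv * r
  }
  sizes <- as.numeric(sizes_all)       # column (j,i), j fastest — matches x

  x <- augment_flips(x, cfg$augment$flip_prob, cfg$vae$patch_points)
  x <- augment_photometric(x, cfg$augment)
  xT <- t(x)                                  # sample-major activations

  enc <- vae_enc_forward(model, xT, keep_cache = TRUE)
  eps <- matrix(rnorm(d * r * b), d, r * b)
  z <- enc$mu + enc$sigma * eps
  dec <- vae_dec_forward(model, z, keep_cache = TRUE)

  recon <- reconstruction_loss(x, t(dec$mu_x), sizes, n_anchors = b)
  kl <- kl_loss(enc$mu, enc$sigma, n_anchors = b, d = d,
                reversed = cfg$loss$kl_reversed)
  msr <- ms_loss_grad(enc$mu[seq_len(dms), , drop = FALSE], r, b,
                      cfg$loss$alpha, cfg$loss$beta, cfg$loss$lambda)
  total <- batch_loss(recon, kl, msr$loss, cfg$loss)
  comps <- c(recon = recon, kl = kl, ms = msr$loss, total = total)
  if (any(!is.finite(comps))) {
    bad <- names(comps)[!is.finite(comps)][1]
    stop("non-finite loss in term '", bad, "' at training time")
  }

  # gradients
  a3 <- sizes^3
  d_mu_x <- sweep(dec$mu_x - xT, 1, a3, "/") * (2 / b)
  if (cfg$loss$kl_reversed) {
    d_mu_kl <- cfg$loss$theta_kl * (enc$mu / enc$sigma^2) / (b * d)
    d_lv_kl <- cfg$loss$theta_kl *
      0.5 * (1 - (1 + enc$mu^2) / enc$sigma^2) / (b * d)
  } else {
    d_mu_kl <- cfg$loss$theta_kl * enc$mu / (b * d)
    # d/d lv of 0.5(sigma^2 - lv) with sigma^2 = exp(lv)
    d_lv_kl <- cfg$loss$theta_kl * 0.5 * (enc$sigma^2 - 1) / (b * d)
  }
  d_mu <- d_mu_kl
  d_mu[seq_len(dms), ] <- d_mu[seq_len(dms), , drop = FALSE] +
    cfg$loss$theta_ms * msr$dE
  grads <- vae_backward(model, x, enc, dec, d_mu_x, d_mu, d_lv_kl, eps)
  list(comps = comps, grads = grads)
}

#' Train the patch VAE
#'
#' Iterates: sample a batch of anchors (round-robin across volumes) with
#' `n_pos` positives each, extract and augment 16^3 patches, forward through
#' the VAE, compute the total loss and take one Adam step. Stops after
#' `anchors_per_stack * length(volumes)` anchors. Deterministic for a fixed
#' seed.
#'
#' @param volumes a [vxr_volume] or list of them.
#' @param config a [train_config()].
#' @param verbose print progress every 25 steps.
#' @return list with `model` (a `vxr_vae`) and `log` (data.frame with one row
#'   per step: step, recon, kl, ms, total).
#' @export
train <- function(volumes, config = train_config(), verbose = FALSE) {
  if (inherits(volumes, "vxr_volume") || (is.array(volumes) && length(dim(volumes)) == 3)) {
    volumes <- list(volumes)
  }
  stopifnot(length(volumes) >= 1)
  nvol <- length(volumes)
  b <- config$batch_anchors
  steps <- (config$anchors_per_stack * nvol) %/% b
  model <- vae_init(config$vae, seed = derive_seed(config$seed, 1))
  opt <- adam_init(model$params)
  log <- matrix(0, steps, 5,
                dimnames = list(NULL, c("step", "recon", "kl", "ms", "total")))
  with_seed(derive_seed(config$seed, 2), {
    for (step in seq_len(steps)) {
      vol_idx <- ((seq_len(b) - 1L + (step - 1L) * b) %% nvol) + 1L
      batch <- train_batch(model, volumes, vol_idx, config)
      upd <- adam_step(model$params, batch$grads, opt, config$lr,
                       config$adam_beta1, config$adam_beta2, config$adam_eps)
      model$params <- upd$params
      opt <- upd$state
      log[step, ] <- c(step, batch$comps)
      if (verbose && step %% 25 == 0) {
        message(sprintf("step %d/%d  recon %.4f  kl %.4f  ms %.4f  total %.4f",
                        step, steps, batch$comps["recon"], batch$comps["kl"],
                        batch$comps["ms"], batch$comps["total"]))
      }
    }
  })
  list(model = model, log = as.data.frame(log))
}
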