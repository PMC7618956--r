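#' Loss configuration
#'
#' Weights and scales of the training objective: a reconstruction term
#' normalized by anchor count and patch volume, a KL term normalized by anchor
#' count and latent dimension, and a multi-similarity metric term on the
#' semantic latent subspace, combined as
#' `L = L_recon + theta_kl * L_kl + theta_ms * L_ms`.
#'
#' `alpha` and `beta` act as positive/negative softmax scales and `lambda` is
#' a margin on the cosine similarity. The scales follow the original
#' multi-similarity formulation (alpha 2, beta 50); the margin and term
#' weights were calibrated on synthetic phantom pilots (lambda 0.5,
#' theta_ms 1). The pairwise statistic is cosine similarity: the sign
#' structure of the loss (positives weighted by `exp(-alpha(S - lambda))`,
#' negatives by `exp(beta(S - lambda))`) rewards large `S` for positives,
#' which is only coherent for a similarity.
#'
#' @param theta_kl KL weight (>= 0).
#' @param theta_ms metric-loss weight (>= 0).
#' @param alpha positive-pair scale (> 0).
#' @param beta negative-pair scale (> 0).
#' @param lambda similarity margin.
#' @param kl_reversed if `TRUE`, compute the KL divergence with the standard
#'   normal as the first argument, `KL(N(0,1) || N(mu, sigma^2))`, instead of
#'   the conventional VAE direction.
#' @return a `vxr_loss_config`.
#' @export
loss_config <- function(theta_kl = 0.1, theta_ms = 1, alpha = 2, beta = 50,
                        lambda = 0.5, kl_reversed = FALSE) {
  stopifnot(alpha > 0, beta > 0, theta_kl >= 0, theta_ms >= 0)
  structure(list(theta_kl = theta_kl, theta_ms = theta_ms, alpha = alpha,
                 beta = beta, lambda = lambda, kl_reversed = kl_reversed),
            class = "vxr_loss_config")
}

#' Reconstruction loss
#'
#' Sum of squared reconstruction errors over all patches (anchors and
#' positives), each normalized by its sampling grid's physical volume `a^3`,
#' divided by the number of anchors `b`:
#' `(1/b) * sum_i ||x_i - mu_x_i||^2 / a_i^3`.
#'
#' @param x input patches, `4096 x n` matrix (or 16^3 array).
#' @param mu_x reconstructions, same shape.
#' @param size physical edge length(s) `a`: scalar or length-`n`.
#' @param n_anchors the anchor count `b` used for normalization (defaults to
#'   `n`, i.e. every patch its own anchor).
#' @return scalar loss (>= 0).
#' @export
reconstruction_loss <- function(x, mu_x, size = 8, n_anchors = NULL) {
  x <- as_patch_matrix(x)
  mu_x <- as_patch_matrix(mu_x)
  if (!identical(dim(x), dim(mu_x))) stop("shape mismatch between x and mu_x")
  n <- ncol(x)
  b <- n_anchors %||% n
  a3 <- rep_len(as.numeric(size), n)^3
  sum(colSums((x - mu_x)^2) / a3) / b
}

#' KL divergence loss
#'
#' Closed-form Gaussian KL to the standard normal, summed over all patches and
#' latent dimensions and normalized by `b * d`:
#' `(1/(b d)) * sum 0.5 (mu^2 + sigma^2 - 1 - log sigma^2)`.
#' With `reversed = TRUE` the argument order is swapped:
#' `KL(N(0,1) || N(mu, sigma^2)) = 0.5 ((1 + mu^2)/sigma^2 - 1 + log sigma^2)`.
#'
#' @param mu latent means, `d x n`.
#' @param sigma latent standard deviations, `d x n`, strictly positive.
#' @param n_anchors anchor count `b` (defaults to `n`).
#' @param d latent dimension (defaults to `nrow(mu)`).
#' @param reversed use the swapped argument order.
#' @return scalar loss (>= 0).
#' @export
kl_loss <- function(mu, sigma, n_anchors = NULL, d = NULL, reversed = FALSE) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  b <- n_anchors %||% ncol(mu)
  d <- d %||% nrow(mu)
  if (reversed) {
    sum(0.5 * ((1 + mu^2) / sigma^2 - 1 + log(sigma^2))) / (b * d)
  } else {
    sum(0.5 * (mu^2 + sigma^2 - 1 - log(sigma^2))) / (b * d)
  }
}

#' Pairwise similarity tensor of semantic embeddings
#'
#' `S[j, i, k, l]` is the cosine similarity between the semantic embedding of
#' sample `i`, replicate `j` and sample `l`, replicate `k`. A zero embedding
#' has similarity 0 to everything (documented convention).
#'
#' @param emb array of semantic embeddings, dim `(1 + n_pos, b, d_ms)`:
#'   replicate, sample, dimension. Replicate 1 is the anchor.
#' @return a 4D array `S` of dim `(1 + n_pos, b, 1 + n_pos, b)`.
#' @export
similarity_tensor <- function(emb) {
  stopifnot(length(dim(emb)) == 3)
  r <- dim(emb)[1]; b <- dim(emb)[2]; d <- dim(emb)[3]
  E <- matrix(emb, r * b, d)              # row (j,i) with j fastest
  nrm <- sqrt(rowSums(E^2))
  U <- E / ifelse(nrm > 0, nrm, 1)
  U[nrm == 0, ] <- 0
  S <- U %*% t(U)
  array(S, c(r, b, r, b))
}

#' Multi-similarity loss on the semantic subspace
#'
#' For each patch (sample `i`, replicate `j`) the loss combines a positive
#' term over that sample's other replicates and a negative term over all
#' replicates of all other samples:
#' \deqn{\frac{1}{b(1+n_{pos})}\sum_{i,j}\Big\{\frac1\alpha\log\big[1+\sum_{k\ne j}
#' e^{-\alpha(S[j,i,k,i]-\lambda)}\big]+\frac1\beta\log\big[1+\sum_{k}\sum_{l\ne i}
#' e^{\beta(S[j,i,k,l]-\lambda)}\big]\Big\}}
#' No pair mining is applied: the loss sums over all pairs as written.
#'
#' @param S a similarity tensor from [similarity_tensor()].
#' @param config a [loss_config()] providing `alpha`, `beta`, `lambda`.
#' @return scalar loss.
#' @export
multi_similarity_loss <- function(S, config = loss_config()) {
  stopifnot(length(dim(S)) == 4)
  r <- dim(S)[1]; b <- dim(S)[2]
  if (b < 2) stop("multi-similarity loss needs at least 2 samples (no negatives exist)")
  Sm <- matrix(S, r * b, r * b)            # row/col index (j,i), j fastest
  ms_loss_from_matrix(Sm, r, b, config$alpha, config$beta, config$lambda)$loss
}

# loss (and optionally gradient w.r.t. the similarity matrix) from the
# flattened M x M similarity matrix, M = r*b, index (j,i) with j fastest
ms_loss_from_matrix <- function(Sm, r, b, alpha, beta, lambda, grad = FALSE) {
  M <- r * b
  sample_of <- rep(seq_len(b), each = r)
  same <- outer(sample_of, sample_of, "==")
  diag_mask <- diag(M) > 0
  pos_mask <- same & !diag_mask
  neg_mask <- !same
  pos_ex <- exp(-alpha * (Sm - lambda)) * pos_mask
  neg_ex <- exp(beta * (Sm - lambda)) * neg_mask
  pos_sum <- rowSums(pos_ex)
  neg_sum <- rowSums(neg_ex)
  loss <- sum(log1p(pos_sum) / alpha + log1p(neg_sum) / beta) / M
  if (!grad) return(list(loss = loss))
  G <- (-pos_ex / (1 + pos_sum) + neg_ex / (1 + neg_sum)) / M
  list(loss = loss, G = G)
}

# fast path used in training: loss and gradient w.r.t. raw semantic
# embeddings E (d_ms x M columns, column (j,i) with j fastest)
ms_loss_grad <- function(E, r, b, alpha, beta, lambda) {
  nrm <- sqrt(colSums(E^2))
  safe <- ifelse(nrm > 0, nrm, 1)
  U <- sweep(E, 2, safe, "/")
  U[, nrm == 0] <- 0
  Sm <- crossprod(U)                        # t(U) %*% U, M x M
  res <- ms_loss_from_matrix(Sm, r, b, alpha, beta, lambda, grad = TRUE)
  W <- res$G + t(res$G)
  dU <- U %*% W                             # d x M
  # through column normalization: dE = (dU - u (u . dU)) / ||e||
  proj <- colSums(U * dU)
  dE <- sweep(dU - sweep(U, 2, proj, "*"), 2, safe, "/")
  dE[, nrm == 0] <- 0
  list(loss = res$loss, dE = dE)
}

#' Total batch loss
#'
#' Weighted sum of the loss terms:
#' `recon + theta_kl * kl + theta_ms * ms`.
#'
#' @param recon reconstruction loss value.
#' @param kl KL loss value.
#' @param ms multi-similarity loss value.
#' @param config a [loss_config()].
#' @return scalar total loss.
#' @export
batch_loss <- function(recon, kl, ms, config = loss_config()) {
  stopifnot(is.finite(recon), is.finite(kl), is.finite(ms))
  recon + config$theta_kl * kl + config$theta_ms * ms
}
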