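#' Clustering configuration
#'
#' Mini-batch k-means settings for clustering per-voxel semantic latents.
#' The streaming update makes clustering scale to volumes with billions of
#' voxels; on the small instances used in tests its inertia stays close to
#' full-batch k-means.
#'
#' @param k number of clusters (>= 2); explored range 4-10 in the published
#'   experiments.
#' @param batch_size vectors per mini-batch.
#' @param n_init independent restarts; the solution with lowest inertia wins.
#' @param max_epochs iteration cap in passes-over-the-data equivalents.
#' @param tol relative center-shift tolerance for early stopping.
#' @param init_sample subsample size for k-means++ initialization.
#' @param reassignment_ratio centers whose accumulated count falls below this
#'   fraction of the largest center's count are re-seeded to a far point of
#'   the current batch (sampled proportionally to squared distance). This
#'   rescues centers stranded on tiny outlier clumps, mirroring standard
#'   mini-batch k-means practice; 0 disables.
#' @return a `vxr_cluster_config`.
#' @export
cluster_config <- function(k, batch_size = 10000, n_init = 3, max_epochs = 200,
                           tol = 1e-4, init_sample = 10000,
                           reassignment_ratio = 0.01) {
  stopifnot(k >= 2, batch_size >= k, n_init >= 1, reassignment_ratio >= 0)
  structure(list(k = as.integer(k), batch_size = as.integer(batch_size),
                 n_init = as.integer(n_init), max_epochs = max_epochs,
                 tol = tol, init_sample = as.integer(init_sample),
                 reassignment_ratio = reassignment_ratio),
            class = "vxr_cluster_config")
}

# squared distances of rows of X (n x d) to rows of C (k x d): n x k
dist2_to_centers <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    if (any(!is.finite(p)) || sum(d2) == 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = p)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ], "-")^2))
  }
  centers
}

minibatch_kmeans_once <- function(X, config) {
  n <- nrow(X); k <- config$k
  init_idx <- sample.int(n, min(config$init_sample, n))
  centers <- kmeanspp_init(X[init_idx, , drop = FALSE], k)
  counts <- numeric(k)
  scale0 <- mean(abs(centers)) + 1e-12
  max_batches <- max(10, ceiling(config$max_epochs * n / config$batch_size))
  stable <- 0L
  rr <- config$reassignment_ratio %||% 0
  for (iter in seq_len(max_batches)) {
    idx <- sample.int(n, min(config$batch_size, n))
    B <- X[idx, , drop = FALSE]
    d2 <- dist2_to_centers(B, centers)
    assign <- max.col(-d2)
    # rescue centers stranded on tiny clumps: re-seed any center whose
    # accumulated count is far below the largest, at a far batch point
    if (rr > 0 && iter > 5L) {
      low <- which(counts < rr * max(counts))
      for (j in low) {
        w <- d2[cbind(seq_len(nrow(B)), assign)]
        pick <- if (sum(w) > 0) sample.int(nrow(B), 1, prob = w) else
          sample.int(nrow(B), 1)
        centers[j, ] <- B[pick, ]
        counts[j] <- 0
        d2[, j] <- rowSums(sweep(B, 2, centers[j, ])^2)
      }
      if (length(low) > 0) assign <- max.col(-d2)
    }
    shift <- 0
    for (j in seq_len(k)) {
      sel <- assign == j
      nj <- sum(sel)
      if (nj == 0) next
      sj <- colSums(B[sel, , drop = FALSE])
      new_c <- (centers[j, ] * counts[j] + sj) / (counts[j] + nj)
      shift <- max(shift, max(abs(new_c - centers[j, ])))
      centers[j, ] <- new_c
      counts[j] <- counts[j] + nj
    }
    if (shift / scale0 < config$tol) {
      stable <- stable + 1L
      if (stable >= 10L) break
    } else stable <- 0L
  }
  centers
}

assign_all <- function(X, centers, block = 100000L) {
  n <- nrow(X)
  lab <- integer(n)
  inertia <- 0
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1, n)
    d2 <- dist2_to_centers(X[s:e, , drop = FALSE], centers)
    lab[s:e] <- max.col(-d2)
    inertia <- inertia + sum(d2[cbind(seq_len(e - s + 1), lab[s:e])])
  }
  list(labels = lab, inertia = inertia)
}

#' Cluster a latent volume into k classes
#'
#' Streams the per-voxel semantic vectors through mini-batch k-means
#' (k-means++ initialization on a subsample, then mini-batch center updates to
#' convergence or an iteration cap; best of `n_init` restarts by full-data
#' inertia) and returns an integer cluster label per voxel. Labels are
#' arbitrary 0-based ids; semantic identity is established only by evaluation
#' matching. Deterministic for a fixed seed.
#'
#' @param latent a `vxr_latent` from [encode_volume()], or an `n x d` matrix
#'   of vectors.
#' @param config a [cluster_config()].
#' @param seed integer seed.
#' @return a [vxr_labels] with labels in `0..k-1` (attributes: `centers`,
#'   `inertia`), or for matrix input a list with `labels` (0-based), `centers`
#'   and `inertia`.
#' @export
cluster_latent <- function(latent, config, seed = 1) {
  is_vol <- inherits(latent, "vxr_latent") ||
    (is.array(latent) && length(dim(latent)) == 4)
  X <- if (is_vol) latent_matrix(latent) else as.matrix(latent)
  if (any(!is.finite(X))) stop("latent contains non-finite values")
  k <- config$k
  best <- NULL
  with_seed(seed, {
    sub <- X[sample.int(nrow(X), min(config$init_sample, nrow(X))), , drop = FALSE]
    ndist <- nrow(unique(sub))
    if (ndist < k && nrow(unique(X)) < k) {
      stop("fewer distinct vectors (", nrow(unique(X)), ") than k = ", k)
    }
    for (r in seq_len(config$n_init)) {
      centers <- minibatch_kmeans_once(X, config)
      res <- assign_all(X, centers)
      if (is.null(best) || res$inertia < best$inertia) {
        best <- list(centers = centers, labels = res$labels,
                     inertia = res$inertia)
      }
    }
  })
  lab0 <- best$labels - 1L
  used <- sort(unique(lab0))
  if (length(used) < k) {
    warning("only ", length(used), " of ", k, " cluster labels are used")
  }
  if (!is_vol) {
    return(list(labels = lab0, centers = best$centers, inertia = best$inertia))
  }
  d <- dim(latent)
  out <- vxr_labels(array(lab0, d[2:4]))
  attr(out, "centers") <- best$centers
  attr(out, "inertia") <- best$inertia
  out
}
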