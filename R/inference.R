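#' Encode every voxel of a volume to its semantic latent representation
#'
#' For each voxel, the fixed-orientation patch of physical edge `size`
#' (default 8, resampled from the 9^3 voxel support onto a 16^3 lattice) is
#' extracted and passed through the encoder; the semantic dimensions of the
#' latent mean are stored. No latent sampling takes place, so the output is
#' deterministic given a checkpoint and independent of the chunk shape.
#'
#' @param model a trained `vxr_vae`.
#' @param volume a [vxr_volume] or 3D array in `[0, 1]`.
#' @param chunk chunk shape for memory-bounded extraction (default 16^3
#'   voxels per chunk).
#' @param size inference patch physical edge (default 8).
#' @param batch_size encoder minibatch size.
#' @param semantic_only keep only the first `semantic_dim` latent dimensions
#'   (default); otherwise all `latent_dim`.
#' @return a `vxr_latent`: a 4D array `(channels, depth, height, width)` with
#'   attributes recording the patch size and model config.
#' @export
encode_volume <- function(model, volume, chunk = c(16, 16, 16), size = 8,
                          batch_size = 1024, semantic_only = TRUE) {
  vol <- as_volume_array(volume)
  shape <- dim(vol)
  dch <- if (semantic_only) model$config$semantic_dim else model$config$latent_dim
  out <- array(0, c(dch, shape))
  it <- dense_inference_patches(vol, chunk = chunk, size = size)
  while (!is.null(ch <- it())) {
    n <- nrow(ch$coords)
    for (s in seq(1, n, by = batch_size)) {
      e <- min(s + batch_size - 1, n)
      mu <- encode(model, ch$patches[, s:e, drop = FALSE])$mu
      co <- ch$coords[s:e, , drop = FALSE]
      flat <- 1 + co[, 1] + shape[1] * (co[, 2] + shape[2] * co[, 3])
      for (c_i in seq_len(dch)) {
        out[c_i + (flat - 1) * dch] <- mu[c_i, ]
      }
    }
  }
  structure(out, class = "vxr_latent", size = size,
            semantic_dim = model$config$semantic_dim)
}

#' @export
print.vxr_latent <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vxr_latent %d channels x %d x %d x %d>\n", d[1], d[2], d[3], d[4]))
  invisible(x)
}

# latent 4D array -> N x d matrix of voxel vectors
latent_matrix <- function(latent) {
  d <- dim(latent)
  t(matrix(latent, d[1], prod(d[2:4])))
}

#' Transformation-invariance score of latent subspaces
#'
#' For patch pairs from [generate_transformed_pairs()], the score of a
#' dimension slice is the mean Euclidean distance between the latent means of
#' original and transformed patches restricted to that slice, divided by the
#' mean pairwise distance among the originals in the same slice
#' (scale-normalized). Lower means more transformation-invariant. Comparing
#' the semantic slice (default dims 1-8) against an equally sized
#' unsupervised slice (dims 9-16) quantifies the disentanglement the metric
#' loss is meant to produce.
#'
#' @param model a trained `vxr_vae`.
#' @param pairs list of pairs from [generate_transformed_pairs()].
#' @param dims_a,dims_b integer vectors of latent dimensions (1-based) for the
#'   two subspaces.
#' @return named numeric `c(score_a, score_b)`.
#' @export
subspace_invariance_score <- function(model, pairs, dims_a = 1:8,
                                      dims_b = 9:16) {
  stopifnot(length(pairs) >= 1)
  if (length(pairs) < 2) stop("need at least 2 originals to normalize the score")
  orig <- vapply(pairs, function(p) as.numeric(p$original), numeric(16^3))
  trans <- vapply(pairs, function(p) as.numeric(p$transformed), numeric(16^3))
  mu_o <- encode(model, orig)$mu
  mu_t <- encode(model, trans)$mu
  score <- function(dims) {
    o <- mu_o[dims, , drop = FALSE]
    tr <- mu_t[dims, , drop = FALSE]
    num <- mean(sqrt(colSums((o - tr)^2)))
    den <- mean(stats::dist(t(o)))
    if (den == 0) return(ifelse(num == 0, 0, Inf))
    num / den
  }
  c(score_a = score(dims_a), score_b = score(dims_b))
}
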