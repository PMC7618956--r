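#' Confusion matrix between prediction and reference labelings
#'
#' `C[i, j]` counts voxels with prediction label `i` (rows) and reference
#' label `j` (columns). Row/column names carry the label values.
#'
#' @param pred predicted [vxr_labels] or integer array.
#' @param ref reference [vxr_labels] or integer array, same shape.
#' @return an `n_pred x n_ref` integer matrix of voxel counts.
#' @export
confusion_matrix <- function(pred, ref) {
  p <- as_label_array(pred)
  r <- as_label_array(ref)
  if (!identical(dim(p), dim(r))) stop("shape mismatch between pred and ref")
  pl <- sort(unique(as.vector(p)))
  rl <- sort(unique(as.vector(r)))
  pi <- match(as.vector(p), pl)
  ri <- match(as.vector(r), rl)
  counts <- tabulate(pi + length(pl) * (ri - 1L), length(pl) * length(rl))
  matrix(counts, length(pl), length(rl), dimnames = list(pred = pl, ref = rl))
}

#' Dice matrix from a confusion matrix
#'
#' `D[i, j] = 2 C[i, j] / (sum_k C[i, k] + sum_l C[l, j])`: twice the
#' intersection over the sum of prediction-class-i size and reference-class-j
#' size. `0/0` is defined as 0.
#'
#' @param C a confusion matrix from [confusion_matrix()].
#' @return a matrix of pairwise Dice coefficients in `[0, 1]`.
#' @export
dice_matrix <- function(C) {
  if (any(C < 0)) stop("confusion matrix must be non-negative")
  denom <- outer(rowSums(C), colSums(C), "+")
  D <- ifelse(denom > 0, 2 * C / denom, 0)
  dimnames(D) <- dimnames(C)
  D
}

# O(n^3) Hungarian algorithm (potentials / shortest augmenting path) for a
# square cost matrix; returns for each row its assigned column.
hungarian_solve <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(n)) a[p[j]] <- j
  a
}

#' Hungarian-matched mean Dice
#'
#' Solves the rectangular linear assignment problem on the cost matrix `-D`
#' (minimum-weight matching maximizes total Dice) and averages the matched
#' Dice entries. The match is a partial bijection of size
#' `n_M = min(n_pred, n_ref)`; with more predicted clusters than reference
#' classes the surplus clusters stay unmatched. Ties between equal-cost
#' optima are broken by the solver's canonical order; the mean Dice is
#' tie-invariant.
#'
#' @param D a Dice matrix from [dice_matrix()].
#' @return a `vxr_match`: list with `pairs` (an `n_M x 2` matrix of
#'   (prediction row, reference column) indices), `dice` (matched Dice
#'   values), and `mean_dice`.
#' @export
hungarian_dice <- function(D) {
  nr <- nrow(D); nc <- ncol(D)
  n <- max(nr, nc)
  cost <- matrix(0, n, n)
  cost[seq_len(nr), seq_len(nc)] <- -D
  a <- hungarian_solve(cost)
  rows <- seq_len(nr)
  keep <- rows <= nr & a[rows] <= nc
  pairs <- cbind(pred = rows[keep], ref = a[rows][keep])
  dice <- D[pairs]
  structure(list(pairs = pairs, dice = dice, mean_dice = mean(dice),
                 n_matched = nrow(pairs)),
            class = "vxr_match")
}

#' @export
print.vxr_match <- function(x, ...) {
  cat(sprintf("<vxr_match %d pairs, mean Dice %.4f>\n", x$n_matched, x$mean_dice))
  for (i in seq_len(x$n_matched)) {
    cat(sprintf("  pred %s -> ref %s  Dice %.4f\n", x$pairs[i, 1], x$pairs[i, 2],
                x$dice[i]))
  }
  invisible(x)
}

#' Per-pair error map
#'
#' For each matched (prediction, reference) pair, flags the voxels assigned to
#' the prediction class that do not belong to its matched reference class
#' (e.g. voxels clustered with mitochondria that are not mitochondria).
#' Unmatched prediction classes are excluded. Pair `m`'s errors are labeled
#' `m`; correct and unmatched voxels are 0.
#'
#' @param pred,ref the label volumes the match was computed from.
#' @param match a `vxr_match` from [hungarian_dice()]. Its pair indices refer
#'   to the sorted unique labels of `pred` and `ref`, as in
#'   [confusion_matrix()].
#' @return a [vxr_labels] error map.
#' @export
error_map <- function(pred, ref, match) {
  p <- as_label_array(pred)
  r <- as_label_array(ref)
  if (!identical(dim(p), dim(r))) stop("shape mismatch between pred and ref")
  pl <- sort(unique(as.vector(p)))
  rl <- sort(unique(as.vector(r)))
  out <- array(0L, dim(p))
  for (m in seq_len(match$n_matched)) {
    pi <- pl[match$pairs[m, 1]]
    rj <- rl[match$pairs[m, 2]]
    out[p == pi & r != rj] <- m
  }
  vxr_labels(out)
}

#' Evaluate an unsupervised segmentation against a reference
#'
#' Convenience wrapper computing the confusion matrix, Dice matrix, Hungarian
#' match, and error map in one call.
#'
#' @param pred predicted cluster labels.
#' @param ref reference labels.
#' @return list with `confusion`, `dice`, `match`, `errors`.
#' @export
evaluate_segmentation <- function(pred, ref) {
  C <- confusion_matrix(pred, ref)
  D <- dice_matrix(C)
  m <- hungarian_dice(D)
  list(confusion = C, dice = D, match = m, errors = error_map(pred, ref, m))
}
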