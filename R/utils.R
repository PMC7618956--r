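`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' All stage- and region-level randomness in the package flows from one master
#' seed through fixed offsets, so a single integer reproduces a whole run.
#'
#' @param seed master seed (integer).
#' @param offset fixed integer offset identifying the consumer.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 16807) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

lrelu <- function(x, slope = 0.1) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

lrelu_grad <- function(pre, slope = 0.1) {
  g <- matrix(1, nrow(pre), ncol(pre))
  g[pre < 0] <- slope
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Sample uniform random 3D rotation matrices
#'
#' Uniform over SO(3) via normalized random quaternions.
#'
#' @param n number of rotations.
#' @return an `n x 9` matrix; each row is a 3x3 rotation stored row-major.
#' @export
random_rotations <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  )
}

# the 24 axis-aligned (proper) rotations, rows row-major
rot90_group <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- matrix(0, 0, 9)
  for (p in perms) {
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
      R <- matrix(0, 3, 3)
      R[1, p[1]] <- s1; R[2, p[2]] <- s2; R[3, p[3]] <- s3
      if (abs(det(R) - 1) < 1e-9) out <- rbind(out, as.vector(t(R)))
    }
  }
  out
}

identity_rows <- function(n) {
  matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), n, 9)
}
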