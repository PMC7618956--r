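# Independent brute-force oracles used to validate the vectorized / C++
# implementations. These are deliberately written as naive loops.

# trilinear interpolation with mirror padding at one 0-based (z,y,x) point
oracle_trilinear <- function(vol, pt) {
  refl <- function(t, n) {
    if (n == 1) return(0)
    per <- 2 * (n - 1)
    t <- t - floor(t / per) * per
    if (t > n - 1) t <- per - t
    t
  }
  d <- dim(vol)
  z <- refl(pt[1], d[1]); y <- refl(pt[2], d[2]); x <- refl(pt[3], d[3])
  z0 <- min(max(floor(z), 0), d[1] - 2)
  y0 <- min(max(floor(y), 0), d[2] - 2)
  x0 <- min(max(floor(x), 0), d[3] - 2)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) fz else 1 - fz) * (if (dy) fy else 1 - fy) *
      (if (dx) fx else 1 - fx)
    acc <- acc + w * vol[z0 + dz + 1, y0 + dy + 1, x0 + dx + 1]
  }
  acc
}

# grid lattice coordinates for one sampling grid (matching the extraction
# convention: 16 points spanning edge a, transformed by A, around center)
oracle_grid_coords <- function(center, size, A_row, m = 16) {
  A <- matrix(A_row, 3, 3, byrow = TRUE)
  offs <- size * ((seq_len(m) - 1) / (m - 1) - 0.5)
  coords <- array(0, c(m, m, m, 3))
  for (i in seq_len(m)) for (j in seq_len(m)) for (k in seq_len(m)) {
    coords[i, j, k, ] <- center + A %*% c(offs[i], offs[j], offs[k])
  }
  coords
}

# Eq-style reconstruction loss as a plain loop over patches and voxels
oracle_recon_loss <- function(x, mu_x, sizes, b) {
  total <- 0
  for (i in seq_len(ncol(x))) {
    total <- total + sum((x[, i] - mu_x[, i])^2) / sizes[i]^3
  }
  total / b
}

# closed-form Gaussian KL summed with explicit loops
oracle_kl_loss <- function(mu, sigma, b, d) {
  total <- 0
  for (i in seq_len(ncol(mu))) for (j in seq_len(nrow(mu))) {
    total <- total + 0.5 * (mu[j, i]^2 + sigma[j, i]^2 - 1 - log(sigma[j, i]^2))
  }
  total / (b * d)
}

# multi-similarity loss as the literal quadruple loop over the S tensor
oracle_ms_loss <- function(S, alpha, beta, lambda) {
  r <- dim(S)[1]; b <- dim(S)[2]
  total <- 0
  for (i in seq_len(b)) for (j in seq_len(r)) {
    pos <- 0
    for (k in seq_len(r)) if (k != j) {
      pos <- pos + exp(-alpha * (S[j, i, k, i] - lambda))
    }
    neg <- 0
    for (k in seq_len(r)) for (l in seq_len(b)) if (l != i) {
      neg <- neg + exp(beta * (S[j, i, k, l] - lambda))
    }
    total <- total + log(1 + pos) / alpha + log(1 + neg) / beta
  }
  total / (b * r)
}

# cosine similarity tensor as plain loops
oracle_similarity_tensor <- function(emb) {
  r <- dim(emb)[1]; b <- dim(emb)[2]
  S <- array(0, c(r, b, r, b))
  for (j in seq_len(r)) for (i in seq_len(b)) {
    for (k in seq_len(r)) for (l in seq_len(b)) {
      u <- emb[j, i, ]; v <- emb[k, l, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      S[j, i, k, l] <- if (nu == 0 || nv == 0) 0 else sum(u * v) / (nu * nv)
    }
  }
  S
}

# exhaustive maximization of mean matched Dice over all partial bijections of
# size min(nrow, ncol)
oracle_best_assignment <- function(D) {
  nr <- nrow(D); nc <- ncol(D)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf
  if (nr <= nc) {
    for (cols in perms(seq_len(nc))) {
      s <- sum(D[cbind(seq_len(nr), cols[seq_len(nr)])])
      if (s > best) best <- s
    }
    best / nr
  } else {
    for (rows in perms(seq_len(nr))) {
      s <- sum(D[cbind(rows[seq_len(nc)], seq_len(nc))])
      if (s > best) best <- s
    }
    best / nc
  }
}

# random Dice-like matrix (entries in [0,1])
random_dice_matrix <- function(nr, nc) {
  matrix(runif(nr * nc), nr, nc)
}
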