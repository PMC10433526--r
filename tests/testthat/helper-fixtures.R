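# shared fixture builders and independent oracles

kB <- 0.0083144621

# random SPD covariance with eigenvalues in [lo, hi] (nm^2)
random_spd <- function(lo = 0.004, hi = 0.016) {
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  ev <- runif(3, lo, hi)
  Q %*% diag(ev) %*% t(Q)
}

random_component <- function(span = 0.1) {
  memmi::gaussianComponent(runif(1, 0.5, 2), runif(3, -span, span), random_spd())
}

# independent normalised Gaussian density (no package code)
dens_gauss <- function(X, mu, S) {
  Si <- solve(S)
  d <- sweep(X, 2, mu)
  q <- rowSums((d %*% Si) * d)
  exp(-0.5 * q) / sqrt((2 * pi)^3 * det(S))
}

# brute-force midpoint quadrature of the overlap integral on a fine grid
quad_overlap <- function(a, b) {
  wa <- a@weight; wb <- b@weight
  Sa <- a@cov; Sb <- b@cov
  Sp <- solve(solve(Sa) + solve(Sb))
  mup <- as.numeric(Sp %*% (solve(Sa, a@mean) + solve(Sb, b@mean)))
  ev <- eigen(Sp, symmetric = TRUE, only.values = TRUE)$values
  h <- sqrt(min(ev)) / 3
  ext <- 8 * sqrt(max(ev))
  g <- seq(-ext, ext, by = h)
  X <- as.matrix(expand.grid(x = g + mup[1], y = g + mup[2], z = g + mup[3]))
  sum(wa * dens_gauss(X, a@mean, Sa) * wb * dens_gauss(X, b@mean, Sb)) * h^3
}

# small analytic voxel map rendered from a known mixture (independent of
# package voxelize): values in nm^-3 on an angstrom grid
render_map <- function(weights, means, covs, origin, spacing, dims) {
  origin <- rep_len(origin, 3); spacing <- rep_len(spacing, 3)
  dims <- rep_len(dims, 3)
  gx <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  gy <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  gz <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  X <- 0.1 * as.matrix(expand.grid(x = gx, y = gy, z = gz))
  v <- numeric(nrow(X))
  for (k in seq_along(weights))
    v <- v + weights[k] * dens_gauss(X, means[k, ], covs[, , k])
  memmi::voxelMap(array(v, dims), origin, spacing)
}

# central finite differences of a scalar function of an N x 3 matrix
fd_gradient <- function(f, X, h = 1e-5) {
  G <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X)))
    for (c in seq_len(ncol(X))) {
      Xp <- X; Xp[i, c] <- Xp[i, c] + h
      Xm <- X; Xm[i, c] <- Xm[i, c] - h
      G[i, c] <- (f(Xp) - f(Xm)) / (2 * h)
    }
  G
}

# ensemble with explicit frames (list of N x 3) and weights
make_ensemble <- function(frames, weights = NULL, meta = NULL) {
  n <- length(frames)
  if (is.null(weights)) weights <- rep(1 / n, n)
  N <- nrow(frames[[1]])
  if (is.null(meta))
    meta <- data.frame(chain = "A", resid = seq_len(N), resname = "BEA",
                       name = "CA", element = "C", class = "core")
  new("WeightedEnsemble",
      coords = array(unlist(frames), c(N, 3, n)), meta = meta,
      weights = weights / sum(weights),
      provenance = data.frame(replica = 1L, step = seq_len(n)))
}

# quick small toy systems reused across files
tiny_chain <- function(seed = 1, chiBarrier = 12.5, tailK = 1) {
  memmi::makeToyFibril(1, 2, 2, seed = seed, chiBarrier = chiBarrier,
                       tailDihedralK = tailK)
}
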