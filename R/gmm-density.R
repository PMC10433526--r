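#' Construct a single Gaussian density component
#'
#' @param weight positive scale factor (density integral carried by the
#'   component).
#' @param mean centre, length-3, nm.
#' @param cov 3x3 symmetric positive-definite covariance, nm^2; a scalar is
#'   taken as an isotropic variance.
#' @return a [GaussianComponent-class].
#' @examples
#' g <- gaussianComponent(1, c(0, 0, 0), 0.01)
#' @export
gaussianComponent <- function(weight, mean, cov) {
  if (length(cov) == 1) cov <- diag(3) * cov
  new("GaussianComponent", weight = as.numeric(weight),
      mean = as.numeric(mean), cov = cov)
}

#' Construct a Gaussian mixture map
#'
#' @param weights numeric vector of K positive component weights.
#' @param means K x 3 matrix of centres (nm).
#' @param covs 3 x 3 x K covariance array (nm^2), or a length-K vector of
#'   isotropic variances.
#' @param label `"data"` or `"model"`.
#' @return a [GaussianMixtureMap-class].
#' @export
gmmMap <- function(weights, means, covs, label = "data") {
  K <- length(weights)
  means <- matrix(as.numeric(means), ncol = 3)
  if (!is.array(covs) || length(dim(covs)) != 3) {
    v <- rep_len(as.numeric(covs), K)
    covs <- vapply(v, function(s) diag(3) * s, diag(3))
  }
  for (k in seq_len(K))                       # enforce exact symmetry
    covs[, , k] <- (covs[, , k] + t(covs[, , k])) / 2
  new("GaussianMixtureMap", weights = as.numeric(weights), means = means,
      covs = covs, label = label)
}

#' Overlap integral of two Gaussian components
#'
#' The closed form of \eqn{\int \omega_a G_a(x)\,\omega_b G_b(x)\,dx}:
#' \eqn{\omega_a \omega_b\,N(\mu_a-\mu_b;\,0,\,\Sigma_a+\Sigma_b)}.  This is
#' the elementary operation behind both the data self-overlap and the
#' model-to-data forward-model comparison.
#'
#' @param a,b [GaussianComponent-class] objects.
#' @return non-negative scalar overlap density; symmetric in its arguments.
#' @export
gaussianOverlap <- function(a, b) {
  stopifnot(is(a, "GaussianComponent"), is(b, "GaussianComponent"))
  cpp_pair_overlap(a@weight, a@mean, a@cov, b@weight, b@mean, b@cov)
}

# all pairwise overlaps between the components of two mixtures (K1 x K2)
.cross_overlaps <- function(map1, map2) {
  cpp_cross_overlaps(map1@weights, map1@means, as.numeric(map1@covs),
                     map2@weights, map2@means, as.numeric(map2@covs))
}

#' Data-map self-overlap of one component
#'
#' `ov_DD,i`, the total overlap of the whole mixture with its i-th component
#' (the sum over all components j, including j = i).  Used to normalise the
#' forward-model overlap and the neighbor-list threshold.
#'
#' @param map a [GaussianMixtureMap-class].
#' @param i component index (1-based); omit for the full vector.
#' @return scalar (or vector) of self-overlaps, strictly positive.
#' @export
selfOverlap <- function(map, i = NULL) {
  stopifnot(is(map, "GaussianMixtureMap"))
  K <- nComponents(map)
  if (!is.null(i)) {
    if (i < 1 || i > K) stop("component index out of range")
    sum(vapply(seq_len(K), function(j)
      cpp_pair_overlap(map@weights[j], map@means[j, ], map@covs[, , j],
                       map@weights[i], map@means[i, ], map@covs[, , i]), 0))
  } else {
    ov <- .cross_overlaps(map, map)
    colSums(ov)
  }
}

#' Construct a voxel map
#'
#' @param values 3-D numeric array of densities.
#' @param origin centre of the first voxel, angstrom.
#' @param spacing voxel edge lengths, angstrom.
#' @return a [VoxelMap-class].
#' @export
voxelMap <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  new("VoxelMap", origin = as.numeric(origin),
      spacing = rep_len(as.numeric(spacing), 3), values = values)
}

# voxel centres in nm (M x 3) in array order (x fastest)
.voxel_centers_nm <- function(map) {
  d <- dim(map@values)
  gx <- map@origin[1] + (seq_len(d[1]) - 1) * map@spacing[1]
  gy <- map@origin[2] + (seq_len(d[2]) - 1) * map@spacing[2]
  gz <- map@origin[3] + (seq_len(d[3]) - 1) * map@spacing[3]
  0.1 * cbind(rep(gx, times = d[2] * d[3]),
              rep(rep(gy, each = d[1]), times = d[3]),
              rep(gz, each = d[1] * d[2]))
}

# log density of K Gaussians at M points; X (M x 3), returns M x K
.log_gauss <- function(X, means, covs) {
  K <- nrow(means)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    R <- chol(covs[, , k])
    Y <- forwardsolve(t(R), t(X) - means[k, ])
    q <- colSums(Y^2)
    out[, k] <- -0.5 * q - sum(log(diag(R))) - 1.5 * log(2 * pi)
  }
  out
}

.clamp_spd <- function(S, floor) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% (v * t(e$vectors))
}

#' Fit a Gaussian mixture to a voxel map
#'
#' Weighted expectation-maximisation over voxel centres, each centre carrying
#' the (non-negative) voxel density mass as its weight.  Negative voxel
#' values, common in experimental maps, are clipped to zero before fitting.
#' Initialisation is k-means++ on density-weighted voxel centres under the
#' given seed, so the fit is fully deterministic.  Component covariance
#' eigenvalues are floored at `(spacing/2)^2` to prevent collapse onto single
#' voxels.  The total mixture weight equals the total clipped voxel mass
#' times the voxel volume, so the fitted mixture integrates to the map mass.
#'
#' @param voxel a [VoxelMap-class].
#' @param nComponents number of Gaussian components.
#' @param seed integer seed controlling initialisation.
#' @param maxIter maximum EM iterations.
#' @param tol relative log-likelihood change declaring convergence.
#' @return a `"data"`-labelled [GaussianMixtureMap-class] with attributes
#'   `loglik` (the per-iteration weighted log-likelihood trace) and
#'   `converged`.
#' @export
fitGMM <- function(voxel, nComponents, seed = 1L, maxIter = 200L, tol = 1e-8) {
  stopifnot(is(voxel, "VoxelMap"), nComponents >= 1)
  vol_nm3 <- prod(voxel@spacing * 0.1)
  dens <- pmax(as.numeric(voxel@values), 0)
  keep <- dens > 0
  if (sum(keep) < nComponents)
    stop("more components requested than nonzero voxels")
  X <- .voxel_centers_nm(voxel)[keep, , drop = FALSE]
  p <- dens[keep] * vol_nm3
  mass <- sum(p)
  if (mass <= 0) stop("map has no positive density mass after clipping")
  K <- as.integer(nComponents)
  sp_nm <- voxel@spacing * 0.1
  floor_ev <- (min(sp_nm) / 2)^2

  mu <- with_seed(seed, {
    # k-means++ on density-weighted centres
    ctr <- matrix(0, K, 3)
    ctr[1, ] <- X[sample.int(nrow(X), 1, prob = p), ]
    if (K > 1) for (k in 2:K) {
      d2 <- rep(Inf, nrow(X))
      for (kk in seq_len(k - 1))
        d2 <- pmin(d2, rowSums((X - matrix(ctr[kk, ], nrow(X), 3, byrow = TRUE))^2))
      ctr[k, ] <- X[sample.int(nrow(X), 1, prob = d2 * p + 1e-300), ]
    }
    ctr
  })
  covs <- vapply(seq_len(K), function(k) diag(3) * max((2 * mean(sp_nm))^2, floor_ev),
                 diag(3))
  pik <- rep(1 / K, K)

  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    lg <- .log_gauss(X, mu, covs)
    lg <- sweep(lg, 2, log(pik), "+")
    m <- apply(lg, 1, max)
    lse <- m + log(rowSums(exp(lg - m)))
    ll <- sum(p * lse)
    ll_trace <- c(ll_trace, ll)
    g <- exp(lg - lse) * p              # responsibilities scaled by mass
    Nk <- colSums(g)
    Nk <- pmax(Nk, 1e-300)
    pik <- Nk / mass
    mu <- (t(g) %*% X) / Nk
    for (k in seq_len(K)) {
      xc <- X - matrix(mu[k, ], nrow(X), 3, byrow = TRUE)
      S <- crossprod(xc * g[, k], xc) / Nk[k]
      covs[, , k] <- .clamp_spd(S, floor_ev)
    }
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
  }
  out <- gmmMap(pik * mass, mu, covs, label = "data")
  attr(out, "loglik") <- ll_trace
  attr(out, "converged") <- converged
  out
}

#' Render a Gaussian mixture on a voxel grid
#'
#' Evaluates the mixture density at every voxel centre.  The inverse of
#' [fitGMM()]; the sum of values times the voxel volume approximates the
#' total mixture weight when the grid covers the mixture support.  A warning
#' is emitted when the grid does not cover the +-4 sigma support.
#'
#' @param gmm a [GaussianMixtureMap-class] (nm units).
#' @param origin,spacing,dims grid geometry in angstrom / voxel counts.
#' @return a [VoxelMap-class]; values are densities in nm^-3.
#' @export
voxelizeGMM <- function(gmm, origin, spacing, dims) {
  stopifnot(is(gmm, "GaussianMixtureMap"))
  spacing <- rep_len(as.numeric(spacing), 3)
  dims <- rep_len(as.integer(dims), 3)
  vm <- voxelMap(array(0, dims), origin, spacing)
  X <- .voxel_centers_nm(vm)
  lo_nm <- 0.1 * origin
  hi_nm <- 0.1 * (origin + (dims - 1) * spacing)
  sd4 <- 4 * sqrt(vapply(seq_len(nComponents(gmm)),
                         function(k) max(diag(gmm@covs[, , k])), 0))
  lo_need <- apply(gmm@means - sd4, 2, min)
  hi_need <- apply(gmm@means + sd4, 2, max)
  if (any(lo_need < lo_nm - 1e-9) || any(hi_need > hi_nm + 1e-9))
    warning("grid does not cover the mixture's +-4 sigma support")
  lg <- .log_gauss(X, gmm@means, gmm@covs)
  vals <- as.numeric(exp(lg) %*% gmm@weights)
  vm@values <- array(vals, dims)
  vm
}

#' Pearson correlation of two voxel maps
#'
#' Computed over all voxels or an optional voxel subset, enabling the
#' region-wise (e.g. N-tail) correlation analyses.
#'
#' @param a,b [VoxelMap-class] objects on identical grids.
#' @param mask optional logical array (or index vector) selecting voxels.
#' @return correlation in [-1, 1].
#' @export
mapCorrelation <- function(a, b, mask = NULL) {
  stopifnot(is(a, "VoxelMap"), is(b, "VoxelMap"))
  if (!all(dim(a@values) == dim(b@values)) ||
      max(abs(a@spacing - b@spacing)) > 1e-6 ||
      max(abs(a@origin - b@origin)) > 1e-6)
    stop("voxel maps are on different grids")
  va <- as.numeric(a@values); vb <- as.numeric(b@values)
  if (!is.null(mask)) {
    idx <- if (is.logical(mask)) which(as.logical(mask)) else as.integer(mask)
    if (length(idx) == 0) stop("mask selects no voxels")
    va <- va[idx]; vb <- vb[idx]
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("correlation undefined for zero-variance input")
  stats::cor(va, vb)
}
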