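#' Reproducibility benchmarks
#'
#' Self-contained experiments that exercise the package end to end and
#' return the quantities its correctness rests on: the overlap-quadrature
#' check, finite-difference force checks, free-energy recovery on an
#' analytic double well, unbiasing of a harmonic well, error-parameter
#' recovery at known noise, two-state population recovery, and the
#' biased-vs-unbiased transition-rate comparison.  Every experiment is
#' deterministic given its seed; the problem sizes are chosen so the whole
#' set completes in minutes on one CPU.  `scripts/acceptance.R` and the
#' test suite both run these functions, so the numbers they report are
#' produced by exactly the code documented here.
#'
#' @param seed integer master seed.
#' @name benchmarks
NULL

#' Numerical quadrature of a Gaussian-component overlap
#'
#' Midpoint-rule integration of the product of two Gaussian components on a
#' fine grid centred on the product Gaussian — an oracle for the closed
#' form in [gaussianOverlap()], which it never calls.
#'
#' @param a,b [GaussianComponent-class] objects.
#' @param spacingFactor grid spacing as a fraction of the smallest product
#'   standard deviation (spacing = sd / spacingFactor).
#' @param extent half-width of the grid in product standard deviations.
#' @return the quadrature value of the overlap integral.
#' @export
quadratureOverlap <- function(a, b, spacingFactor = 3, extent = 8) {
  Sp <- solve(solve(a@cov) + solve(b@cov))
  mup <- as.numeric(Sp %*% (solve(a@cov, a@mean) + solve(b@cov, b@mean)))
  ev <- eigen(Sp, symmetric = TRUE, only.values = TRUE)$values
  h <- sqrt(min(ev)) / spacingFactor
  half <- extent * sqrt(max(ev))
  g <- seq(-half, half, by = h)
  X <- as.matrix(expand.grid(g + mup[1], g + mup[2], g + mup[3]))
  dens <- function(mu, S) {
    Si <- solve(S)
    d <- sweep(X, 2, mu)
    exp(-0.5 * rowSums((d %*% Si) * d)) / sqrt((2 * pi)^3 * det(S))
  }
  sum(a@weight * dens(a@mean, a@cov) * b@weight * dens(b@mean, b@cov)) * h^3
}

# random anisotropic SPD covariance with eigenvalues in [lo, hi]
.random_spd <- function(lo = 0.004, hi = 0.016) {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  Q %*% diag(stats::runif(3, lo, hi)) %*% t(Q)
}

#' @describeIn benchmarks closed-form overlap vs quadrature on random
#'   anisotropic pairs; returns the per-pair relative errors.
#' @param nPairs number of random component pairs.
#' @export
benchmarkOverlapQuadrature <- function(seed = 1L, nPairs = 50L) {
  with_seed(substream_seed(seed, 11), {
    vapply(seq_len(nPairs), function(k) {
      a <- gaussianComponent(stats::runif(1, 0.5, 2),
                             stats::runif(3, -0.1, 0.1), .random_spd())
      b <- gaussianComponent(stats::runif(1, 0.5, 2),
                             stats::runif(3, -0.1, 0.1), .random_spd())
      q <- quadratureOverlap(a, b)
      abs(gaussianOverlap(a, b) - q) / q
    }, 0)
  })
}

#' @describeIn benchmarks central-finite-difference checks of the overlap
#'   gradient, the metainference restraint force and the bias force;
#'   returns the three max relative errors.
#' @export
benchmarkGradients <- function(seed = 1L) {
  fd <- function(f, X, h = 1e-5) {
    G <- matrix(0, nrow(X), 3)
    for (i in seq_len(nrow(X))) for (c in 1:3) {
      Xp <- X; Xp[i, c] <- Xp[i, c] + h
      Xm <- X; Xm[i, c] <- Xm[i, c] - h
      G[i, c] <- (f(Xp) - f(Xm)) / (2 * h)
    }
    G
  }
  relerr <- function(A, B) max(abs(A - B)) / max(abs(B))
  with_seed(substream_seed(seed, 12), {
    params <- forwardModelParams()
    meta <- data.frame(chain = "A", resid = 1:6, resname = "B", name = "CA",
                       element = "C")
    X0 <- matrix(stats::runif(18, -0.2, 0.2), 6, 3)
    covs <- array(0, c(3, 3, 5))
    for (k in 1:5) covs[, , k] <- .random_spd()
    data <- gmmMap(stats::runif(5, 0.5, 2),
                   matrix(stats::runif(15, -0.3, 0.3), 5), covs)
    ovDD <- selfOverlap(data)

    gOv <- relerr(overlapGradient(conformation(X0, meta), params, data, i = 2),
                  fd(function(X) overlapVector(conformation(X, meta), params,
                                               data)[2], X0))

    err <- errorState(1, 5, ovDD = ovDD, sigmaB = 0.2 * stats::median(ovDD))
    eData <- function(X) {
      av <- overlapVector(conformation(X, meta), params, data)
      metainferenceEnergy(av, ovDD, err, 300)$data
    }
    FF <- restraintForce(conformation(X0, meta), params, data, err = err,
                         avOv = overlapVector(conformation(X0, meta), params,
                                              data),
                         temperature = 300)
    gRest <- relerr(FF, -fd(eData, X0))

    cvs <- list(cvDihedral(1:4, "phi"))
    bias <- biasState(cvs, temperature = 300)
    for (s in c(-2.0, 0.4, 2.6))
      bias <- depositHills(s, bias, 1L, 200)
    X1 <- matrix(stats::rnorm(12, sd = 0.4), 4, 3)
    gBias <- relerr(biasForce(X1, cvs, bias),
                    -fd(function(X) evaluateBias(evaluateCV(X, cvs[[1]]),
                                                 bias), X1, h = 1e-6))
    c(overlapGradient = gOv, restraintForce = gRest, biasForce = gBias)
  })
}

#' @describeIn benchmarks well-tempered parallel-bias recovery of the
#'   analytic chi double well (barrier 12.5 kJ/mol, about 5 kBT at 300 K);
#'   returns the max absolute profile error and the profile itself.
#' @param nSteps,nWalkers run length (steps) and walker count.
#' @export
benchmarkFreeEnergyRecovery <- function(seed = 1L, nSteps = 300000L,
                                        nWalkers = 4L) {
  barrier <- 12.5
  sys <- makeToyFibril(1, 2, 2, seed = 2, chiBarrier = barrier)
  cvs <- list(cvDihedral(sys@chiAtoms[[1]], "chi"))
  cfg <- memmiConfig(nReplicas = nWalkers, nSteps = nSteps, dt = 0.004,
                     friction = 20, seed = substream_seed(seed, 13),
                     saveStride = 200, gamma = 10, h0 = 0.3)
  traj <- runMEMMI(sys, NULL, cvs, cfg)
  grid <- seq(-pi, pi, length.out = 181)
  fes <- freeEnergyProfile(traj@biasState, 1, grid, timeAverage = 0.6,
                           nCheckpoints = 40L)
  Ftrue <- barrier / 2 * (1 + cos(2 * grid))
  Ftrue <- Ftrue - min(Ftrue)
  list(maxAbsErr = max(abs(fes$F - Ftrue)), profile = fes, truth = Ftrue,
       hills = traj@log$hillCounts)
}

#' @describeIn benchmarks unbiasing-weight recovery of the second moment of
#'   a harmonic torsional well under a converged bias; returns the weighted
#'   estimate, the analytic value kBT/k and the relative error.
#' @export
benchmarkHarmonicUnbias <- function(seed = 1L, nSteps = 600000L,
                                    nWalkers = 4L) {
  k <- 60
  sys <- makeToyFibril(1, 2, 2, seed = 2)
  chiRow <- which(sys@dihedralTag == "chi")
  sys@dihedrals[chiRow, 5:8] <- c(k, 1, 0, 2)     # harmonic well at 0
  cvs <- list(cvDihedral(sys@chiAtoms[[1]], "chi"))
  cfg <- memmiConfig(nReplicas = nWalkers, nSteps = nSteps, dt = 0.004,
                     friction = 20, seed = substream_seed(seed, 14),
                     saveStride = 5, gamma = 10, h0 = 0.3)
  traj <- runMEMMI(sys, NULL, cvs, cfg)
  ens <- trajectoryEnsemble(traj)
  phi <- unlist(lapply(traj@replicas, function(rp) {
    n <- length(rp$steps)
    rp$cv[(floor(0.1 * n) + 1):n, 1]
  }))
  est <- sum(ens@weights * phi^2)
  truth <- .kB * 300 / k
  list(estimate = est, truth = truth, relErr = abs(est / truth - 1))
}

#' @describeIn benchmarks Monte-Carlo recovery of known noise scales: for
#'   each sigma* the posterior scale estimate (square root of the mean over
#'   data points of the per-point harmonic mean of sigmaB^2 over the second
#'   half of the chain — the moment the Jeffreys posterior determines:
#'   E[1/sigma^2 | residual] = 1/residual^2) is compared to sigma*;
#'   returns a per-sigma* data.frame.
#' @param sigmaStars noise scales spanning a decade (overlap units).
#' @param nData,nReplicas,nSweeps chain dimensions.
#' @export
benchmarkSigmaRecovery <- function(seed = 1L,
                                   sigmaStars = c(0.02, 0.0632, 0.2),
                                   nData = 400L, nReplicas = 2L,
                                   nSweeps = 12000L) {
  out <- lapply(seq_along(sigmaStars), function(j) {
    ss <- sigmaStars[j]
    with_seed(substream_seed(seed, 20 + j), {
      ovModel <- stats::runif(nData, 1, 3)
      ovSynth <- ovModel + stats::rnorm(nData, 0, ss)
      err <- errorState(nReplicas, nData, ovDD = ovSynth, mcStep = 0.3)
      keepFrom <- floor(nSweeps / 2)
      accPrec <- matrix(0, nReplicas, nData); nAcc <- 0
      for (sw in seq_len(nSweeps)) {
        err <- .mc_sweep(err, ovModel, ovSynth, TRUE)$state
        if (sw > keepFrom) {
          accPrec <- accPrec + 1 / err@sigmaB^2
          nAcc <- nAcc + 1
        }
      }
      est <- sqrt(mean(nAcc / accPrec))
      data.frame(sigmaStar = ss, estimate = est, relErr = abs(est / ss - 1))
    })
  })
  do.call(rbind, out)
}

#' @describeIn benchmarks the method's purpose in miniature: a rigid-armed
#'   one-chain toy fibril with a two-well chi torsion, a data map
#'   synthesized from the two endpoint conformations at populations
#'   70/30 (with thermal blur matching the within-state fluctuations), and
#'   a multi-walker run whose reweighted tail-out population is compared
#'   to 0.70.
#' @export
benchmarkPopulationRecovery <- function(seed = 1L, nSteps = 120000L,
                                        nWalkers = 4L) {
  sys <- makeToyFibril(1, 3, 3, seed = 2, chiBarrier = 15,
                       tailDihedralK = 25, tailAngleK = 300, corePosK = 1000)
  params <- forwardModelParams(resolution = 1.0)
  confOut <- conformation(setChiAngles(sys, angles = pi / 2), sys@meta)
  confIn <- conformation(setChiAngles(sys, angles = -pi / 2), sys@meta)
  dmap <- synthesizeDataMap(list(confOut, confIn), c(0.7, 0.3), params,
                            thermalSd = 0.12)$gmm
  cvs <- list(cvDihedral(sys@chiAtoms[[1]], "chi"))
  cfg <- memmiConfig(nReplicas = nWalkers, nSteps = nSteps, dt = 0.004,
                     friction = 5, seed = substream_seed(seed, 15),
                     saveStride = 40, gamma = 10, h0 = 0.3)
  traj <- runMEMMI(sys, dmap, cvs, cfg, params = params)
  ens <- trajectoryEnsemble(traj)
  chi <- unlist(lapply(traj@replicas, function(rp) {
    n <- length(rp$steps)
    rp$cv[(floor(0.1 * n) + 1):n, 1]
  }))
  pOut <- sum(ens@weights * (chi > 0))
  list(pOut = pOut, truth = 0.7, absErr = abs(pOut - 0.7), traj = traj,
       dataMap = dmap)
}

#' @describeIn benchmarks transition counts of a biased vs an unbiased
#'   mirror chi torsion over equal steps, pooled over `nSeeds` independent
#'   runs; `h0 = 0` gives the no-bias symmetry control.
#' @param nSeeds independent runs pooled.
#' @param h0 initial hill height (0 disables the bias).
#' @export
benchmarkAcceleration <- function(seed = 1L, nSeeds = 3L, nSteps = 100000L,
                                  h0 = 0.3) {
  counts <- t(vapply(seq_len(nSeeds), function(s) {
    sys <- makeToyFibril(2, 3, 2, seed = 4, chiBarrier = 15,
                         tailDihedralK = 4, stackSpacing = 0.9)
    cvPair <- list(cvDihedral(sys@chiAtoms[[1]], "chi_biased"),
                   cvDihedral(sys@chiAtoms[[2]], "chi_mirror"))
    cfg <- memmiConfig(nReplicas = 1, nSteps = nSteps, dt = 0.004,
                       friction = 5, seed = substream_seed(seed, 30 + s),
                       saveStride = 10, gamma = 10, h0 = h0)
    traj <- runComparison(sys, NULL, cvPair, cfg)
    cv <- traj@replicas[[1]]$cv
    c(biased = transitionCount(cv[, 1], c(-pi, 0), periodic = TRUE),
      mirror = transitionCount(cv[, 2], c(-pi, 0), periodic = TRUE))
  }, c(biased = 0, mirror = 0)))
  tot <- colSums(counts)
  list(counts = counts, totals = tot,
       ratio = tot["biased"] / max(tot["mirror"], 1),
       poissonZ = abs(tot["biased"] - tot["mirror"]) / sqrt(sum(tot)))
}

#' @describeIn benchmarks recovery of a known 3-component mixture by
#'   [fitGMM()]; returns the correlation between the rendered fit and the
#'   input map.
#' @export
benchmarkGMMFitRecovery <- function(seed = 1L) {
  means <- rbind(c(-0.4, 0, 0), c(0.4, 0.2, 0), c(0, -0.3, 0.3))
  covs <- array(0, c(3, 3, 3))
  covs[, , 1] <- diag(3) * 0.012
  covs[, , 2] <- diag(c(0.02, 0.008, 0.008))
  covs[, , 3] <- diag(3) * 0.01
  truth <- gmmMap(c(2, 1.5, 1), means, covs)
  origin <- c(-12, -10, -8); spacing <- 1.2; dims <- c(22, 20, 18)
  vox <- voxelizeGMM(truth, origin, spacing, dims)
  fit <- fitGMM(vox, 3, seed = substream_seed(seed, 40))
  back <- voxelizeGMM(fit, origin, spacing, dims)
  list(correlation = mapCorrelation(back, vox), fit = fit)
}
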