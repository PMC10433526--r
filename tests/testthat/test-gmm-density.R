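test_that("closed-form Gaussian overlap agrees with numerical quadrature", {
  set.seed(11)
  # isotropic self-overlap has a textbook value
  g <- gaussianComponent(1, c(0, 0, 0), 0.01)
  expect_equal(gaussianOverlap(g, g), 1 / sqrt((2 * pi)^3 * det(diag(3) * 0.02)))
  for (k in 1:10) {
    a <- random_component(); b <- random_component()
    expect_equal(gaussianOverlap(a, b), quad_overlap(a, b), tolerance = 1e-6)
  }
})

test_that("overlap is symmetric and decays over separated means", {
  set.seed(12)
  for (k in 1:100) {
    a <- random_component(); b <- random_component()
    expect_identical(gaussianOverlap(a, b), gaussianOverlap(b, a))
  }
  s <- 0.05
  near <- gaussianOverlap(gaussianComponent(1, c(0, 0, 0), s^2),
                          gaussianComponent(1, c(0, 0, 0), s^2))
  far <- gaussianOverlap(gaussianComponent(1, c(0, 0, 0), s^2),
                         gaussianComponent(1, c(10 * s, 0, 0), s^2))
  expect_lt(far, 1e-10 * near)
})

test_that("component construction rejects invalid covariances", {
  expect_error(gaussianComponent(1, c(0, 0, 0), diag(c(1, -1, 1)) * 0.01),
               "positive-definite")
  expect_error(gaussianComponent(-1, c(0, 0, 0), 0.01), "positive")
})

test_that("self-overlap matches single-component formula and brute force", {
  g1 <- gmmMap(2, matrix(c(0, 0, 0), 1), 0.01)
  expect_equal(selfOverlap(g1, 1), 4 / sqrt((2 * pi)^3 * det(diag(3) * 0.02)))

  # distant second component leaves the self-overlap unchanged
  g2 <- gmmMap(c(2, 2), rbind(c(0, 0, 0), c(100 * 0.1, 0, 0)), c(0.01, 0.01))
  expect_equal(selfOverlap(g2, 1), selfOverlap(g1, 1), tolerance = 1e-8)

  set.seed(13)
  K <- 20
  covs <- array(0, c(3, 3, K))
  for (k in seq_len(K)) covs[, , k] <- random_spd()
  map <- gmmMap(runif(K, 0.5, 2), matrix(runif(3 * K, -0.2, 0.2), K), covs)
  # independent double loop using the plain density formula
  oracle <- vapply(seq_len(K), function(i) {
    tot <- 0
    for (j in seq_len(K)) {
      S <- covs[, , i] + covs[, , j]
      tot <- tot + map@weights[i] * map@weights[j] *
        dens_gauss(map@means[j, , drop = FALSE], map@means[i, ], S)
    }
    tot
  }, 0)
  expect_equal(selfOverlap(map), oracle, tolerance = 1e-12)
  expect_error(selfOverlap(map, 21), "out of range")
})

test_that("voxelize places the mode, conserves mass and is linear", {
  g <- gmmMap(3, matrix(c(0.5, 0.5, 0.5), 1), 0.01)   # mean at 5 A
  vm <- voxelizeGMM(g, origin = c(-5, -5, -5), spacing = 1, dims = 21)
  expect_equal(which(vm@values == max(vm@values), arr.ind = TRUE)[1, ],
               c(dim1 = 11, dim2 = 11, dim3 = 11))
  mass <- sum(vm@values) * prod(vm@spacing * 0.1)
  expect_equal(mass, 3, tolerance = 0.01)
  # halving the spacing halves the Riemann error too (both already < 1%)
  vm2 <- voxelizeGMM(g, origin = c(-5, -5, -5), spacing = 0.5, dims = 41)
  expect_equal(sum(vm2@values) * prod(vm2@spacing * 0.1), 3, tolerance = 0.01)
  gd <- gmmMap(6, matrix(c(0.5, 0.5, 0.5), 1), 0.01)
  vmd <- voxelizeGMM(gd, origin = c(-5, -5, -5), spacing = 1, dims = 21)
  expect_equal(vmd@values, 2 * vm@values)
  expect_warning(voxelizeGMM(g, origin = c(0, 0, 0), spacing = 1, dims = 4),
                 "support")
})

test_that("map correlation behaves as a Pearson coefficient with masks", {
  set.seed(14)
  v <- array(rnorm(16^3), c(16, 16, 16))
  a <- voxelMap(v); b <- voxelMap(-v + 3)
  expect_equal(mapCorrelation(a, a), 1.0)
  expect_equal(mapCorrelation(a, b), -1.0)
  n <- 1e5
  x <- voxelMap(array(rnorm(n), c(50, 50, 40)))
  y <- voxelMap(array(rnorm(n), c(50, 50, 40)))
  expect_lt(abs(mapCorrelation(x, y)), 3 / sqrt(n))
  mask <- array(FALSE, c(16, 16, 16)); mask[1:4, , ] <- TRUE
  expect_true(abs(mapCorrelation(a, a, mask) - 1) < 1e-12)
  expect_error(mapCorrelation(a, x), "different grids")
  expect_error(mapCorrelation(a, voxelMap(array(1, c(16, 16, 16)))),
               "zero-variance")
})

test_that("GMM fitting recovers a known mixture and is deterministic", {
  means <- rbind(c(-0.4, 0, 0), c(0.4, 0.2, 0), c(0, -0.3, 0.3))
  covs <- array(0, c(3, 3, 3))
  covs[, , 1] <- diag(3) * 0.012
  covs[, , 2] <- diag(c(0.02, 0.008, 0.008))
  covs[, , 3] <- diag(3) * 0.01
  w <- c(2, 1.5, 1)
  truth <- render_map(w, means, covs, origin = c(-12, -10, -8),
                      spacing = 1.2, dims = c(22, 20, 18))
  fit <- fitGMM(truth, 3, seed = 7)
  expect_true(attr(fit, "converged"))
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) > -1e-8 * abs(ll[-1])))
  refit <- fitGMM(truth, 3, seed = 7)
  expect_identical(fit@weights, refit@weights)
  expect_identical(fit@means, refit@means)
  # total weight equals clipped voxel mass x voxel volume
  expect_equal(sum(fit@weights),
               sum(pmax(truth@values, 0)) * prod(truth@spacing * 0.1))
  back <- voxelizeGMM(fit, c(-12, -10, -8), 1.2, c(22, 20, 18))
  expect_gte(mapCorrelation(back, truth), 0.99)
})

test_that("single-Gaussian fit lands on the true mean within one voxel", {
  truth <- render_map(1, matrix(c(0.05, -0.03, 0.08), 1),
                      array(diag(3) * 0.01, c(3, 3, 3))[, , 1, drop = FALSE],
                      origin = c(-8, -8, -8), spacing = 1, dims = c(17, 17, 17))
  fit <- fitGMM(truth, 1, seed = 3)
  expect_lt(max(abs(fit@means[1, ] - c(0.05, -0.03, 0.08))), 0.1)  # 1 A in nm
  expect_error(fitGMM(truth, 1e6, seed = 1), "nonzero voxels")
})

test_that("fit quality is monotone in component count on a 4-blob map", {
  means <- rbind(c(-0.45, -0.3, 0), c(0.45, -0.3, 0),
                 c(-0.45, 0.35, 0.1), c(0.45, 0.35, -0.1))
  covs <- array(rep(diag(3) * 0.009, 4), c(3, 3, 4))
  truth <- render_map(rep(1, 4), means, covs, origin = c(-10, -9, -6),
                      spacing = 1.2, dims = c(18, 17, 12))
  best <- vapply(c(1, 2, 4, 8), function(K) {
    max(vapply(1:5, function(s) {
      f <- fitGMM(truth, K, seed = s, maxIter = 80)
      # low-K fits legitimately spill over the grid edge; the correlation
      # is still well-defined there
      v <- suppressWarnings(voxelizeGMM(f, c(-10, -9, -6), 1.2, c(18, 17, 12)))
      mapCorrelation(v, truth)
    }, 0))
  }, 0)
  expect_true(all(diff(best) >= -1e-6))
  expect_gte(best[4], 0.95)
})
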