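# minimal hand-built two-bead harmonic system for thermostat checks
two_bead <- function(k = 1000, r0 = 0.38) {
  meta <- data.frame(chain = "A", resid = 1:2, resname = "COR", name = "CA",
                     element = "C", class = "core")
  new("ToySystem", meta = meta, masses = c(1, 1),
      bonds = matrix(c(1, 2, r0, k), 1),
      angles = matrix(0, 0, 5), dihedrals = matrix(0, 0, 8),
      dihedralTag = character(0), pairs = matrix(0L, 0, 2),
      eps = 0, sigmaRep = 0.1, posK = c(0, 0), chiAtoms = list(),
      refCoords = rbind(c(0, 0, 0), c(r0, 0, 0)))
}

test_that("toy fibril construction bookkeeping is exact and deterministic", {
  sys <- makeToyFibril(4, 6, 3, seed = 9)
  expect_equal(nrow(sys@meta), 36L)
  # per chain: 8 backbone bonds; lattice: 6 vertical + 5 diagonal per interface
  expect_equal(nrow(sys@bonds), 4 * 8 + 3 * (6 + 5))
  expect_equal(nrow(sys@angles), 4 * 7)
  expect_equal(nrow(sys@dihedrals), 4 * 6)
  expect_equal(sum(sys@dihedralTag == "chi"), 4L)
  expect_equal(sum(sys@dihedralTag == "core"), 4 * 3)

  sys2 <- makeToyFibril(4, 6, 3, seed = 9)
  expect_identical(sys@refCoords, sys2@refCoords)
  expect_false(identical(sys@refCoords, makeToyFibril(4, 6, 3, seed = 10)@refCoords))

  core_k <- sys@dihedrals[sys@dihedralTag == "core", 5]
  tail_k <- sys@dihedrals[sys@dihedralTag == "tail", 5]
  expect_gt(min(core_k), max(tail_k))

  # the reference conformation has every chi at +pi/2
  for (at in sys@chiAtoms)
    expect_equal(evaluateCV(sys@refCoords, cvDihedral(at)), pi / 2,
                 tolerance = 1e-6)
})

test_that("synthetic data maps are population-weighted model mixtures", {
  sys <- makeToyFibril(2, 3, 2, seed = 4)
  params <- forwardModelParams()
  confA <- conformation(setChiAngles(sys, angles = pi / 2), sys@meta)
  confB <- conformation(setChiAngles(sys, angles = -pi / 2), sys@meta)

  one <- synthesizeDataMap(list(confA), 1, params)
  mA <- modelGMM(confA, params)
  expect_equal(one$gmm@weights, mA@weights)
  expect_equal(one$gmm@means, mA@means)

  two <- synthesizeDataMap(list(confA, confB), c(0.7, 0.3), params)
  expect_equal(sum(two$gmm@weights),
               0.7 * sum(mA@weights) + 0.3 * sum(modelGMM(confB, params)@weights))
  expect_error(synthesizeDataMap(list(confA, confB), c(0.7, 0.2), params),
               "sum to 1")
  expect_error(synthesizeDataMap(list(confA), c(0.7, 0.3), params),
               "one population per conformation")

  # a two-state envelope is not either endpoint
  g <- list(origin = two$voxel@origin, spacing = two$voxel@spacing,
            dims = dim(two$voxel@values))
  vA <- synthesizeDataMap(list(confA), 1, params, grid = g)$voxel
  vB <- synthesizeDataMap(list(confB), 1, params, grid = g)$voxel
  expect_lt(mapCorrelation(two$voxel, vA), 0.999)
  expect_lt(mapCorrelation(two$voxel, vB), 0.999)

  # seeded voxel noise is reproducible
  n1 <- synthesizeDataMap(list(confA), 1, params, noiseSd = 0.05, grid = g,
                          seed = 3)$voxel
  n2 <- synthesizeDataMap(list(confA), 1, params, noiseSd = 0.05, grid = g,
                          seed = 3)$voxel
  expect_identical(n1@values, n2@values)
})

test_that("toy force field forces are exact gradients of its energy", {
  sys <- makeToyFibril(2, 4, 3, seed = 3)
  set.seed(71)
  X <- sys@refCoords + matrix(rnorm(3 * nrow(sys@meta), 0, 0.03),
                              nrow(sys@meta), 3)
  ff <- memmi:::.toy_ff(sys, X)
  fd <- fd_gradient(function(Y) memmi:::.toy_ff(sys, Y)$energy, X, h = 1e-6)
  expect_equal(ff$forces, -fd, tolerance = 1e-6)
})

test_that("thermostatted bond fluctuations satisfy equipartition", {
  k <- 1000; r0 <- 0.38; T <- 300
  sys <- two_bead(k, r0)
  cfg <- memmiConfig(nReplicas = 1, nSteps = 60000, dt = 0.002, friction = 20,
                     temperature = T, seed = 11, saveStride = 10)
  traj <- runMEMMI(sys, NULL, list(), cfg)
  co <- traj@replicas[[1]]$coords
  rr <- sqrt(colSums((co[2, , ] - co[1, , ])^2))
  dev2 <- (rr - r0)^2
  # radial-measure oracle: <(r-r0)^2> under r^2 exp(-beta k (r-r0)^2 / 2)
  beta <- 1 / (kB * T)
  num <- integrate(function(r) (r - r0)^2 * r^2 * exp(-beta * k * (r - r0)^2 / 2),
                   0, r0 * 4)$value
  den <- integrate(function(r) r^2 * exp(-beta * k * (r - r0)^2 / 2),
                   0, r0 * 4)$value
  expected <- num / den
  blocks <- matrix(dev2[1:6000], ncol = 20)
  se <- sd(colMeans(blocks)) / sqrt(20)
  expect_lt(abs(mean(dev2) - expected), 3 * se + 0.02 * expected)
})

test_that("energy is conserved in the NVE limit", {
  sys <- two_bead(1000)
  cfg <- memmiConfig(nReplicas = 1, nSteps = 10000, dt = 0.0005, friction = 0,
                     seed = 2, saveStride = 10)
  traj <- runMEMMI(sys, NULL, list(), cfg)
  e <- traj@replicas[[1]]$energy
  tot <- e[, "prior"] + e[, "kinetic"]
  drift <- abs(unname(coef(lm(tot ~ seq_along(tot)))[2])) * length(tot)
  expect_lt(drift, 1e-3)
})

test_that("runs are reproducible and reduce to the unbiased/undata limits", {
  sys <- makeToyFibril(1, 2, 2, seed = 6)
  cvs <- list(cvDihedral(sys@chiAtoms[[1]], "chi"))
  confA <- conformation(setChiAngles(sys, angles = pi / 2), sys@meta)
  dmap <- synthesizeDataMap(list(confA), 1)$gmm
  cfg <- memmiConfig(nReplicas = 2, nSteps = 600, seed = 8, saveStride = 20)

  t1 <- runMEMMI(sys, dmap, cvs, cfg)
  t2 <- runMEMMI(sys, dmap, cvs, cfg)
  expect_identical(t1@replicas, t2@replicas)
  expect_identical(t1@errorState@sigmaB, t2@errorState@sigmaB)

  # no CVs: every frame weight is 1 and V_PB is constant (pure restraint run)
  emmi <- runMEMMI(sys, dmap, list(), cfg)
  expect_true(all(vapply(emmi@replicas, function(r) all(r$weight == 1), TRUE)))
  expect_true(all(vapply(emmi@replicas, function(r) all(r$vpb == 0), TRUE)))
  expect_true(all(vapply(emmi@replicas, function(r)
    all(abs(r$energy[, "total"] - rowSums(r$energy[, c("prior", "data", "error")]))
        < 1e-10), TRUE)))

  # no data: data and error energies are identically zero (plain PBMetaD)
  pbm <- runMEMMI(sys, NULL, cvs, cfg)
  expect_true(all(vapply(pbm@replicas, function(r)
    all(r$energy[, c("data", "error")] == 0), TRUE)))
  expect_gt(sum(vapply(pbm@biasState@hills, nrow, 1L)), 0)

  # numerical blow-up is reported with step and replica
  bad <- memmiConfig(nReplicas = 1, nSteps = 200, dt = 50, seed = 1)
  expect_error(runMEMMI(sys, NULL, list(), bad), "step.*replica|non-finite")
})

test_that("biased and mirror free-energy profiles agree where both are low", {
  sys <- makeToyFibril(2, 3, 2, seed = 4, chiBarrier = 8, tailDihedralK = 4,
                       stackSpacing = 0.9)
  cvPair <- list(cvDihedral(sys@chiAtoms[[1]], "chi_biased"),
                 cvDihedral(sys@chiAtoms[[2]], "chi_mirror"))
  cfg <- memmiConfig(nReplicas = 1, nSteps = 2e5, dt = 0.004, friction = 5,
                     seed = 8, saveStride = 10, gamma = 10, h0 = 0.3)
  traj <- runComparison(sys, NULL, cvPair, cfg)
  kBT <- kB * 300
  grid <- seq(-pi, pi, length.out = 37)
  fes_b <- freeEnergyProfile(traj@biasState, 1, (grid[-1] + grid[-37]) / 2)
  rp <- traj@replicas[[1]]
  n <- length(rp$steps); keep <- (floor(0.1 * n) + 1):n
  w <- unbiasWeight(rp$vpb[keep], 300)
  mcv <- rp$cv[keep, 2]
  bin <- findInterval(mcv, grid, all.inside = TRUE)
  pw <- tapply(w, factor(bin, levels = 1:36), sum); pw[is.na(pw)] <- 0
  Fh <- -kBT * log(pw / sum(pw)); Fh <- Fh - min(Fh)
  low <- which(is.finite(Fh) & Fh < 4 & fes_b$F < 4)
  expect_gt(length(low), 8)
  expect_lt(max(abs(fes_b$F[low] - Fh[low])), 1.0)
})

test_that("only the biased member of a symmetric CV pair is accelerated", {
  sys <- makeToyFibril(2, 3, 2, seed = 12, chiBarrier = 15)
  cvPair <- list(cvDihedral(sys@chiAtoms[[1]], "chi_biased"),
                 cvDihedral(sys@chiAtoms[[2]], "chi_mirror"))
  cfg <- memmiConfig(nReplicas = 1, nSteps = 30000, seed = 5, saveStride = 10,
                     friction = 2)
  traj <- runComparison(sys, NULL, cvPair, cfg)
  expect_equal(traj@log$biasMask, c(TRUE, FALSE))
  expect_equal(length(traj@biasState@cvnames), 1L)
  cv <- traj@replicas[[1]]$cv
  nb <- transitionCount(cv[, 1], c(-pi, 0), periodic = TRUE)
  nu <- transitionCount(cv[, 2], c(-pi, 0), periodic = TRUE)
  expect_gt(nb, nu)   # full rate-ratio statistics live in the acceptance suite
})
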