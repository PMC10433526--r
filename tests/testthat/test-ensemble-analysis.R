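rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

test_that("resampling follows the weights, the seed and the multinomial law", {
  set.seed(61)
  frames <- lapply(1:10, function(i) matrix(rnorm(9), 3, 3))
  degenerate <- make_ensemble(frames, weights = c(rep(0, 4), 1, rep(0, 5)))
  rs <- resampleEnsemble(degenerate, 20, seed = 1)
  expect_true(all(rs@provenance$step == 5))
  expect_equal(frameWeights(rs), rep(1 / 20, 20))

  uniform <- make_ensemble(frames)
  big <- resampleEnsemble(uniform, 1e4, seed = 2)
  counts <- table(factor(big@provenance$step, levels = 1:10))
  sigma <- sqrt(1e4 * 0.1 * 0.9)
  expect_true(all(abs(counts - 1000) < 4 * sigma))

  expect_identical(resampleEnsemble(uniform, 50, seed = 7)@provenance,
                   resampleEnsemble(uniform, 50, seed = 7)@provenance)
})

test_that("RMSD removes rigid-body motion and matches a search oracle", {
  set.seed(62)
  A <- matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(rmsdCA(A, A), 0)
  B <- sweep(A %*% rot_z(0.8), 2, c(1, -2, 0.5), "+")
  expect_lt(rmsdCA(A, B), 1e-8)

  C <- A + matrix(rnorm(30, sd = 0.1), 10, 3)
  r_pkg <- rmsdCA(A, C)
  # oracle: numerical minimisation over Euler angles from many starts
  ctr <- function(X) sweep(X, 2, colMeans(X))
  Ac <- ctr(A); Cc <- ctr(C)
  obj <- function(ang) {
    R <- rot_z(ang[1]) %*%
      matrix(c(1, 0, 0, 0, cos(ang[2]), sin(ang[2]),
               0, -sin(ang[2]), cos(ang[2])), 3, 3) %*% rot_z(ang[3])
    sqrt(mean(rowSums((Ac - Cc %*% R)^2)))
  }
  best <- min(vapply(1:40, function(i)
    optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-12))$value, 0))
  expect_equal(r_pkg, best, tolerance = 1e-3)
  expect_error(rmsdCA(A, matrix(0, 4, 3)), "match")
})

test_that("Lindemann parameters recover analytic fluctuations and labels", {
  # rigid 4-bead core plus one fluctuating bead
  core <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0, 0.4, 0), c(0, 0, 0.4))
  meta <- data.frame(chain = "A", resid = 1:5,
                     resname = c(rep("COR", 4), "TLA"), name = "CA",
                     element = "C", class = c(rep("core", 4), "tail"))
  k <- 50; T <- 300; a <- 0.45
  sdev <- sqrt(kB * T / k)
  set.seed(63)
  frames <- lapply(1:10000, function(i)
    rbind(core, c(0.2, 0.2, 0.2) + rnorm(3, 0, sdev)))
  ens <- make_ensemble(frames, meta = meta)
  prof <- lindemann(ens, selection = "sidechain", a = a)
  expect_equal(prof$deltaL[prof$resid == 5], sqrt(3 * kB * T / k) / a,
               tolerance = 0.05)

  still <- make_ensemble(frames[c(1, 1, 1)], meta = meta)
  p0 <- lindemann(still, selection = "backbone", a = a)
  expect_lt(max(p0$deltaL), 1e-8)   # zero up to superposition round-off
  expect_true(all(p0$label == "solid"))

  # the 0.15 threshold splits 0.14 / 0.16 exactly
  for (d in c(0.14, 0.16)) {
    fr <- list(rbind(core, c(0.2 + d * a, 0.2, 0.2)),
               rbind(core, c(0.2 - d * a, 0.2, 0.2)))
    pd <- lindemann(make_ensemble(fr, meta = meta), "sidechain", a = a)
    expect_equal(pd$deltaL[pd$resid == 5], d, tolerance = 1e-10)
    expect_equal(pd$label[pd$resid == 5], if (d < 0.15) "solid" else "liquid")
  }

  expect_error(lindemann(ens, selection = integer(0)), "empty")
})

test_that("weighted ensembles and their resamples agree on Lindemann values", {
  core <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0, 0.4, 0), c(0, 0, 0.4))
  meta <- data.frame(chain = "A", resid = 1:5,
                     resname = c(rep("COR", 4), "TLA"), name = "CA",
                     element = "C", class = c(rep("core", 4), "tail"))
  set.seed(64)
  frames <- lapply(1:2000, function(i)
    rbind(core, c(0.2, 0.2, 0.2) + rnorm(3, 0, 0.06)))
  w <- runif(2000)
  ens <- make_ensemble(frames, weights = w, meta = meta)
  dl5 <- function(p) p$deltaL[p$resid == 5]
  ref <- dl5(lindemann(ens, "sidechain", a = 0.45))
  r1 <- dl5(lindemann(resampleEnsemble(ens, 1e3, seed = 1), "sidechain", 0.45))
  r2 <- dl5(lindemann(resampleEnsemble(ens, 1e4, seed = 1), "sidechain", 0.45))
  expect_lt(abs(r2 - ref) / ref, 0.03)
  expect_lt(abs(r2 - ref), abs(r1 - ref) + 0.02 * ref)
})

test_that("GROMOS clustering matches a brute-force oracle and handles weights", {
  set.seed(65)
  base <- matrix(rnorm(15, sd = 0.3), 5, 3)
  frames <- lapply(1:50, function(i) base + matrix(rnorm(15, sd = 0.08), 5, 3))
  w <- runif(50)
  ens <- make_ensemble(frames, weights = w)
  cutoff <- 0.12
  cl <- gromosCluster(ens, cutoff)

  # independent brute-force pass over an explicitly computed distance matrix
  D <- matrix(0, 50, 50)
  for (i in 1:49) for (j in (i + 1):50)
    D[i, j] <- D[j, i] <- rmsdCA(frames[[i]], frames[[j]])
  wn <- w / sum(w)
  left <- 1:50; memb <- rep(NA_integer_, 50); meds <- integer(0); k <- 0
  while (length(left)) {
    k <- k + 1
    score <- sapply(left, function(i) sum(wn[left][D[i, left] <= cutoff]))
    med <- left[which.max(score)]
    inC <- left[D[med, left] <= cutoff]
    memb[inC] <- k; meds <- c(meds, med); left <- setdiff(left, inC)
  }
  expect_equal(cl$membership, memb)
  expect_equal(cl$medoids, meds)
  expect_equal(sum(cl$populations), 1)

  # all-identical frames collapse into one full-population cluster
  same <- make_ensemble(frames[c(1, 1, 1, 1)])
  cs <- gromosCluster(same, 0.01)
  expect_equal(cs$populations, 1)

  # duplicated frames with uniform weights == deduplicated multiplicity weights
  dup <- make_ensemble(frames[c(1, 1, 2, 3, 3, 3)])
  ded <- make_ensemble(frames[1:3], weights = c(2, 1, 3))
  cd <- gromosCluster(dup, cutoff); ce <- gromosCluster(ded, cutoff)
  expect_equal(sort(cd$populations), sort(ce$populations))

  # two tight, internally different groups far beyond the cutoff split exactly
  other <- matrix(rnorm(15, sd = 2), 5, 3)   # internal RMSD >> 10 x cutoff
  mix <- make_ensemble(c(lapply(1:6, function(i)
                           base + matrix(rnorm(15, sd = 0.02), 5, 3)),
                         lapply(1:4, function(i)
                           other + matrix(rnorm(15, sd = 0.02), 5, 3))))
  cm <- gromosCluster(mix, cutoff)
  expect_equal(max(cm$membership), 2L)
  expect_equal(unname(cm$populations), c(0.6, 0.4))
})

test_that("half-vs-half convergence reports detect stationarity and drift", {
  set.seed(66)
  stateA <- matrix(rnorm(15, sd = 0.3), 5, 3)
  stateB <- matrix(rnorm(15, sd = 2), 5, 3)   # internally distinct state
  draw <- function(n, p) lapply(1:n, function(i)
    (if (runif(1) < p) stateA else stateB) + matrix(rnorm(15, sd = 0.05), 5, 3))

  stationary <- make_ensemble(c(draw(400, 0.6), draw(400, 0.6)))
  rep1 <- convergenceReport(stationary, cutoff = 0.5)
  expect_lt(rep1$maxDiff, 0.05)

  disjoint <- make_ensemble(c(draw(50, 1), draw(50, 0)))
  rep2 <- convergenceReport(disjoint, cutoff = 0.5)
  expect_gt(rep2$maxDiff, 0.95)

  tiny <- make_ensemble(draw(2, 0.5))
  expect_error(convergenceReport(tiny, 0.5), "two frames per half")
})

test_that("relative data-error profiles implement the overlap normalisation", {
  set.seed(67)
  K <- 6
  covs <- array(0, c(3, 3, K))
  for (k in seq_len(K)) covs[, , k] <- random_spd()
  data <- gmmMap(runif(K, 0.5, 2), matrix(runif(3 * K, -0.2, 0.2), K), covs)
  ovDD <- selfOverlap(data)

  tr0 <- array(1e-300, c(3, K, 10))    # effectively zero errors
  expect_lt(max(relativeErrorProfile(tr0, data)$relative), 1e-250)

  trc <- array(0.25, c(3, K, 10))
  expect_equal(relativeErrorProfile(trc, data)$relative, 0.25 / ovDD)

  trr <- array(runif(3 * K * 10, 0.1, 1), c(3, K, 10))
  oracle <- numeric(K)
  for (i in seq_len(K)) oracle[i] <- mean(trr[, i, ]) / ovDD[i]
  prof <- relativeErrorProfile(trr, data)
  expect_equal(prof$relative, oracle, tolerance = 1e-12)
  expect_equal(prof$mean, mean(oracle), tolerance = 1e-12)
})

test_that("transition counting respects boundaries, wrap and hysteresis", {
  expect_equal(transitionCount(rep(0.3, 100), 0), 0L)
  expect_equal(transitionCount(seq(-1, 1, length.out = 50), 0), 1L)
  expect_error(transitionCount(numeric(0), 0), "empty")

  set.seed(68)
  # telegraph with 17 programmed switches plus sub-band noise
  levels <- rep(c(-1, 1), length.out = 18)
  sig <- unlist(lapply(levels, function(l) rep(l, 40))) + rnorm(18 * 40, 0, 0.02)
  expect_equal(transitionCount(sig, 0, hysteresis = 0.1), 17L)
  # tiny hysteresis lets the noise chatter through occasionally; the band
  # restores the programmed count
  expect_gte(transitionCount(sig, 0, hysteresis = 0), 17L)
})
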