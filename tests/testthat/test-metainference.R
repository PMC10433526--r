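test_that("weighted replica averaging reduces correctly and matches the formula", {
  set.seed(41)
  ov <- matrix(runif(4 * 6), 4, 6)
  expect_equal(ensembleAverageOverlap(ov, rep(1, 4)), colMeans(ov))
  expect_equal(ensembleAverageOverlap(ov, c(0, 0, 1, 0)), ov[3, ])
  w <- runif(4)
  oracle <- colSums(ov * w) / sum(w)
  expect_equal(ensembleAverageOverlap(ov, w), oracle, tolerance = 1e-14)
  expect_error(ensembleAverageOverlap(ov, rep(0, 4)), "positive")
})

test_that("metainference energy has the Gaussian-likelihood structure", {
  set.seed(42)
  K <- 8; R <- 3; T <- 310
  ovDD <- runif(K, 1, 3)
  err <- errorState(R, K, ovDD = ovDD,
                    sigmaB = matrix(runif(R * K, 0.1, 1), R, K),
                    sigmaSEM = runif(K, 0, 0.2))
  kBT <- kB * T

  # zero residual: only normalisation and the error prior remain
  e0 <- metainferenceEnergy(ovDD, ovDD, err, T)
  s2 <- sweep(err@sigmaB^2, 2, err@sigmaSEM^2, "+")
  expect_equal(e0$data, kBT * sum(0.5 * log(2 * pi * s2)), tolerance = 1e-12)
  expect_equal(e0$error, kBT * sum(log(err@sigmaB)), tolerance = 1e-12)

  # independent re-implementation on a random instance
  avOv <- ovDD + rnorm(K, 0, 0.3)
  e <- metainferenceEnergy(avOv, ovDD, err, T, priorEnergy = 5)
  oracle <- 5 + kBT * sum(log(err@sigmaB))
  for (r in 1:R) for (i in 1:K)
    oracle <- oracle + kBT * ((ovDD[i] - avOv[i])^2 / (2 * s2[r, i]) +
                              0.5 * log(2 * pi * s2[r, i]))
  expect_equal(e$total, oracle, tolerance = 1e-12)
  expect_equal(e$total, e$prior + e$data + e$error, tolerance = 1e-12)

  # quadratic residual dependence of the mismatch part
  e1 <- metainferenceEnergy(ovDD + 0.1, ovDD, err, T)
  e2 <- metainferenceEnergy(ovDD + 0.2, ovDD, err, T)
  mism1 <- e1$data - e0$data
  mism2 <- e2$data - e0$data
  expect_equal(mism2 / mism1, 4, tolerance = 1e-10)

  # permuting replicas (rows of sigmaB) leaves the energy unchanged
  perm <- c(3, 1, 2)
  errP <- errorState(R, K, ovDD = ovDD, sigmaB = err@sigmaB[perm, ],
                     sigmaSEM = err@sigmaSEM)
  expect_equal(metainferenceEnergy(avOv, ovDD, errP, T)$total, e0$total +
                 (metainferenceEnergy(avOv, ovDD, err, T)$total - e0$total),
               tolerance = 1e-12)
})

test_that("sigma Monte Carlo respects bounds, determinism and its prior", {
  K <- 50; R <- 4
  ovDD <- rep(2, K)
  err <- errorState(R, K, sigmaMin = 1e-3, sigmaMax = 10, mcStep = 1.0)
  avOv <- ovDD

  r1 <- mcUpdateSigma(err, avOv, ovDD, 300, seed = 9)
  r2 <- mcUpdateSigma(err, avOv, ovDD, 300, seed = 9)
  expect_identical(r1$state@sigmaB, r2$state@sigmaB)

  # long prior-only chain: samples follow the Jeffreys density
  st <- err
  for (s in 1:1200)
    st <- mcUpdateSigma(st, avOv, ovDD, 300, seed = 1000 + s,
                        likelihood = FALSE)$state
  x <- as.numeric(st@sigmaB)
  expect_true(all(x >= 1e-3 & x <= 10))
  # Jeffreys CDF on [sigmaMin, sigmaMax] is linear in log sigma
  u <- log(x / 1e-3) / log(10 / 1e-3)
  D <- suppressWarnings(stats::ks.test(u, "punif")$statistic)
  expect_lt(D, 1.63 / sqrt(length(u)))   # 1% critical value

  # proposals beyond sigmaMax are rejected, the entry stays put
  hi <- errorState(1, 1, sigmaMin = 1, sigmaMax = 1 + 1e-12,
                   sigmaB = 1 + 1e-12, mcStep = 0.5)
  out <- mcUpdateSigma(hi, 0.5, 1, 300, seed = 2, likelihood = FALSE)
  expect_equal(out$state@sigmaB[1, 1], 1 + 1e-12)
})

test_that("windowed sigma_SEM matches closed forms and boundary rules", {
  K <- 3
  constant <- matrix(2, 50, K)
  expect_equal(updateSigmaSEM(constant, 20), rep(0, K))

  a <- 1; b <- 3; W <- 20
  alt <- matrix(rep(c(a, b), W / 2), W, K)
  # sample sd of an even a,b alternation is |a-b|/2 * sqrt(W/(W-1))
  expect_equal(updateSigmaSEM(alt, W),
               rep(abs(a - b) / (2 * sqrt(W - 1)), K), tolerance = 1e-12)

  set.seed(44)
  h <- matrix(rnorm(10 * K), 10, K)
  expect_equal(updateSigmaSEM(h, 1e6), apply(h, 2, sd) / sqrt(10))
  expect_message(out <- updateSigmaSEM(h[1, , drop = FALSE], 10, fallback = 0.7),
                 "fallback")
  expect_equal(out, rep(0.7, K))
})

test_that("restraint forces match finite differences of the data energy", {
  params <- forwardModelParams()
  meta <- data.frame(chain = "A", resid = 1:6, resname = "B", name = "CA",
                     element = "C")
  set.seed(45)
  X0 <- matrix(runif(18, -0.2, 0.2), 6, 3)
  conf <- conformation(X0, meta)
  data <- modelGMM(conf, params); data@label <- "data"
  ovDD <- selfOverlap(data)
  err1 <- errorState(1, nComponents(data), ovDD = ovDD,
                     sigmaB = stats::median(ovDD) * 0.1)

  # model == data, single replica: residual zero, forces vanish
  F0 <- restraintForce(conf, params, data, err = err1,
                       avOv = overlapVector(conf, params, data),
                       temperature = 300)
  expect_lt(max(abs(F0)), 1e-10)

  # displaced replica with partial weight: force = -dE/dx through <ov>
  Xd <- X0 + matrix(rnorm(18, 0, 0.05), 6, 3)
  confd <- conformation(Xd, meta)
  err2 <- errorState(2, nComponents(data), ovDD = ovDD,
                     sigmaB = matrix(stats::median(ovDD) * c(0.05, 0.2),
                                     2, nComponents(data)))
  wfrac <- 0.35
  ovOther <- overlapVector(conf, params, data)    # frozen other replica
  energy_of <- function(X) {
    av <- wfrac * overlapVector(conformation(X, meta), params, data) +
      (1 - wfrac) * ovOther
    metainferenceEnergy(av, ovDD, err2, 300)$data
  }
  FF <- restraintForce(confd, params, data, err = err2,
                       avOv = wfrac * overlapVector(confd, params, data) +
                         (1 - wfrac) * ovOther,
                       weightFraction = wfrac, temperature = 300)
  fd <- -fd_gradient(energy_of, Xd, h = 1e-5)
  expect_equal(FF, fd, tolerance = 1e-4)

  # pruned atoms feel no restraint
  farX <- X0; farX[6, ] <- farX[6, ] + 50
  confFar <- conformation(farX, meta)
  nl <- buildNeighborList(modelGMM(confFar, params), data, cutoff = 0.01)
  Ffar <- restraintForce(confFar, params, data, nl, err1,
                         avOv = overlapVector(confFar, params, data, nl),
                         temperature = 300)
  expect_true(all(Ffar[6, ] == 0))
})
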