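cis_conf <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
trans_conf <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))

test_that("torsion CV follows the sign convention and wraps to [-pi, pi)", {
  spec <- cvDihedral(1:4)
  expect_equal(evaluateCV(cis_conf, spec), 0)
  expect_equal(evaluateCV(trans_conf, spec), -pi)   # pi reported as -pi

  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(evaluateCV(bad, spec), "degenerate|collinear")

  set.seed(51)
  X <- matrix(rnorm(12, sd = 0.5), 4, 3)
  g <- evaluateCV(X, spec, gradient = TRUE)
  fd <- fd_gradient(function(Y) evaluateCV(Y, spec), X, h = 1e-6)
  expect_equal(g$grad, fd, tolerance = 1e-5)
})

test_that("coordination CV takes the n/m limit exactly and differentiates", {
  X <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  spec <- cvCoordination(1, 2, r0 = 0.5, n = 6, m = 12)
  expect_equal(evaluateCV(X, spec), 0.5)   # r == r0 limit

  set.seed(52)
  X2 <- matrix(runif(18, 0, 0.6), 6, 3)
  spec2 <- cvCoordination(1:3, 4:6, r0 = 0.35)
  v <- evaluateCV(X2, spec2, gradient = TRUE)
  expect_gte(v$value, 0)
  expect_lte(v$value, 9)                   # bounded by the pair count
  fd <- fd_gradient(function(Y) evaluateCV(Y, spec2), X2, h = 1e-6)
  expect_equal(v$grad, fd, tolerance = 1e-5)
})

test_that("parallel-bias combination follows the log-sum-exp form", {
  kBT <- kB * 300
  cvs2 <- list(cvDihedral(1:4, "a"), cvDihedral(1:4, "b"))
  b2 <- biasState(cvs2, temperature = 300)
  expect_equal(evaluateBias(c(0.1, -0.2), b2), -kBT * log(2))

  cvs1 <- list(cvDihedral(1:4, "a"))
  b1 <- biasState(cvs1, temperature = 300, gamma = 10, h0 = 0.3)
  b1 <- depositHills(0.4, b1, walker = 1L, step = 200)
  # single CV: V_PB equals V_G, the hill height at its centre
  expect_equal(evaluateBias(0.4, b1), 0.3, tolerance = 1e-12)

  # two CVs, V_G1 = h at the point, V_G2 = 0
  b2h <- depositHills(c(0.4, 10), b2, walker = 1L, step = 200)
  b2h@hills[[2]] <- b2h@hills[[2]][0, ]      # strip the second CV's hill
  h <- b2h@hills[[1]]$height[1]
  expect_equal(evaluateBias(c(0.4, 0), b2h),
               -kBT * log(exp(-h / kBT) + 1), tolerance = 1e-12)
})

test_that("well-tempered deposits shrink on stacked hills and obey the stride", {
  kBT <- kB * 300
  cvs <- list(cvDihedral(1:4, "a"))
  b <- biasState(cvs, temperature = 300, gamma = 10, h0 = 0.3)
  b <- depositHills(0.0, b, walker = 1L, step = 200)
  b <- depositHills(0.0, b, walker = 1L, step = 400)
  h <- b@hills[[1]]$height
  expect_equal(h[1], 0.3)
  expect_equal(h[2], 0.3 * exp(-h[1] / (kBT * 9)), tolerance = 1e-12)

  binf <- biasState(cvs, temperature = 300, gamma = Inf, h0 = 0.3)
  binf <- depositHills(0, binf, 1L, 200)
  binf <- depositHills(0, binf, 1L, 400)
  expect_equal(binf@hills[[1]]$height, c(0.3, 0.3))

  expect_error(depositHills(0, b, 1L, step = 301), "off-stride")
})

test_that("adaptive widths track recent fluctuations within the clamp", {
  cvs <- list(cvDihedral(1:4, "a"))
  b <- biasState(cvs, temperature = 300)
  hist <- matrix(rnorm(200, 0, 0.08), ncol = 1)
  b1 <- depositHills(0, b, 1L, 200, cvHistory = hist)
  expect_equal(b1@hills[[1]]$width, max(sd(hist[, 1]), 0.05), tolerance = 0.05)
  wide <- matrix(runif(200, -pi, pi), ncol = 1)
  b2 <- depositHills(0, b, 1L, 200, cvHistory = wide)
  expect_lte(b2@hills[[1]]$width, 0.15)     # cap
  b3 <- depositHills(0, b, 1L, 200)         # no history: the floor
  expect_equal(b3@hills[[1]]$width, 0.05)
})

test_that("walker merges are commutative, additive and duplicate-free", {
  cvs <- list(cvDihedral(1:4, "a"))
  base <- biasState(cvs)
  A <- depositHills(0.5, base, walker = 1L, step = 200)
  B <- depositHills(-0.5, base, walker = 2L, step = 200)
  AB <- syncWalkers(list(A, B))
  BA <- syncWalkers(list(B, A))
  expect_identical(AB@hills, BA@hills)
  expect_equal(nrow(AB@hills[[1]]), 2L)
  expect_equal(evaluateBias(0.2, AB),
               evaluateBias(0.2, A) + evaluateBias(0.2, B), tolerance = 1e-12)
  # re-merging the merged state adds nothing
  expect_identical(syncWalkers(list(AB, A))@hills, AB@hills)

  other <- biasState(list(cvDihedral(1:4, "zz")))
  expect_error(syncWalkers(list(A, other)), "mismatched")
})

test_that("bias forces match finite differences and respect periodicity", {
  set.seed(53)
  X <- matrix(rnorm(12, sd = 0.4), 4, 3)
  cvs <- list(cvDihedral(1:4, "a"))
  b <- biasState(cvs, temperature = 300)
  expect_equal(biasForce(X, cvs, b), matrix(0, 4, 3))  # no hills, no force

  for (s in c(-2.5, 0.3, 3.0)) {
    centre <- ((s + pi) %% (2 * pi)) - pi
    b <- depositHills(centre, b, 1L, step = 200)
  }
  FF <- biasForce(X, cvs, b)
  fd <- -fd_gradient(function(Y)
    evaluateBias(evaluateCV(Y, cvs[[1]]), b), X, h = 1e-6)
  expect_equal(FF, fd, tolerance = 1e-4)

  # potential is continuous across the periodic boundary
  vl <- evaluateBias(pi - 1e-9, b)
  vr <- evaluateBias(-pi + 1e-9, b)
  expect_equal(vl, vr, tolerance = 1e-6)
})

test_that("unbiasing weights are exponential, guarded and shift-invariant", {
  kBT <- kB * 300
  expect_equal(unbiasWeight(0, 300), 1)
  expect_equal(unbiasWeight(kBT * log(2), 300), 2)
  v <- c(0, 1, 2, 5)
  w <- unbiasWeight(v, 300)
  ws <- unbiasWeight(v + 17, 300)
  expect_equal(w / sum(w), ws / sum(ws), tolerance = 1e-12)
  huge <- unbiasWeight(c(1e5, 1e5 + 1), 300)
  expect_true(all(is.finite(huge)))
})

test_that("free-energy profiles invert the bias with the gamma factor", {
  cvs <- list(cvDihedral(1:4, "a"))
  grid <- seq(-pi, pi, length.out = 2001)   # resolve floor-width hills
  b <- biasState(cvs, temperature = 300, gamma = 10)
  expect_error(freeEnergyProfile(b, 1, grid), "no hills")
  b <- depositHills(0.3, b, 1L, 200)
  f <- freeEnergyProfile(b, 1, grid)
  expect_equal(min(f$F), 0)
  h <- b@hills[[1]]
  # the -gamma/(gamma-1) scaling read off at the hill centre
  expect_equal(max(f$F) - min(f$F), (10 / 9) * h$height, tolerance = 1e-3)

  binf <- biasState(cvs, gamma = Inf)
  binf <- depositHills(0.3, binf, 1L, 200)
  finf <- freeEnergyProfile(binf, 1, grid)
  expect_equal(max(finf$F) - min(finf$F), binf@hills[[1]]$height,
               tolerance = 1e-3)
})
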