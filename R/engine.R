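#' Run configuration
#'
#' Defaults mirror the production protocol at toy scale: the density
#' restraint is refreshed every 2 MD steps, neighbor lists every 100 steps,
#' hills are deposited every 200 steps, and analyses discard the first 10%
#' of frames as equilibration.
#'
#' @param nReplicas number of walkers/replicas.
#' @param nSteps MD steps.
#' @param dt time step, ps.
#' @param friction Langevin friction, 1/ps.
#' @param temperature kelvin.
#' @param seed master seed; every replica runs a substream derived from
#'   (seed, replica id), and the error Monte Carlo its own.
#' @param nlCutoff relative overlap threshold of the neighbor list.
#' @param restraintStride steps between density-restraint refreshes.
#' @param neighborStride steps between neighbor-list rebuilds.
#' @param hillStride steps between hill deposits.
#' @param saveStride steps between saved frames.
#' @param equilFraction initial fraction of frames analyses discard.
#' @param gamma,h0 well-tempered bias factor and initial hill height.
#' @param widthFloor,widthCap optional per-CV clamps on the adaptive hill
#'   width (defaults chosen by [biasState()]).
#' @param mcStep log-space Monte-Carlo step for sigmaB.
#' @param sigmaMinFactor,sigmaMaxFactor bounds of the sampled sigmaB in
#'   units of the median data self-overlap.
#' @param sigmaSEMMode `"windowed"` (on-the-fly standard error) or
#'   `"constant"`.
#' @param sigmaSEMWindow window length (restraint evaluations).
#' @param sigmaSEMConstant value used in constant mode / as fallback.
#' @return a validated configuration list.
#' @export
memmiConfig <- function(nReplicas = 4L, nSteps = 10000L, dt = 0.004,
                        friction = 5, temperature = 300, seed = 1L,
                        nlCutoff = 0.01,
                        restraintStride = 2L, neighborStride = 100L,
                        hillStride = 200L, saveStride = 20L,
                        equilFraction = 0.1, gamma = 10, h0 = 0.3,
                        widthFloor = NULL, widthCap = NULL,
                        mcStep = 0.05, sigmaMinFactor = 1e-4,
                        sigmaMaxFactor = 10,
                        sigmaSEMMode = c("windowed", "constant"),
                        sigmaSEMWindow = 200L, sigmaSEMConstant = 0) {
  sigmaSEMMode <- match.arg(sigmaSEMMode)
  cfg <- list(nReplicas = as.integer(nReplicas), nSteps = as.integer(nSteps),
              dt = dt, friction = friction, temperature = temperature,
              seed = as.integer(seed), nlCutoff = nlCutoff,
              restraintStride = as.integer(restraintStride),
              neighborStride = as.integer(neighborStride),
              hillStride = as.integer(hillStride),
              saveStride = as.integer(saveStride),
              equilFraction = equilFraction, gamma = gamma, h0 = h0,
              widthFloor = widthFloor, widthCap = widthCap,
              mcStep = mcStep, sigmaMinFactor = sigmaMinFactor,
              sigmaMaxFactor = sigmaMaxFactor,
              sigmaSEMMode = sigmaSEMMode,
              sigmaSEMWindow = as.integer(sigmaSEMWindow),
              sigmaSEMConstant = sigmaSEMConstant)
  stopifnot(cfg$dt > 0, cfg$nSteps >= 1, cfg$nReplicas >= 1,
            all(unlist(cfg[c("restraintStride", "neighborStride",
                             "hillStride", "saveStride")]) >= 1))
  cfg
}

# RNG substream bookkeeping: draw from stream `id`, preserving the others.
.stream_new <- function(seed, ids) {
  states <- lapply(ids, function(i) {
    set.seed(substream_seed(seed, i))
    get(".Random.seed", envir = globalenv())
  })
  names(states) <- as.character(ids)
  states
}

.stream_draw <- function(streams, id, expr) {
  assign(".Random.seed", streams[[as.character(id)]], envir = globalenv())
  val <- eval.parent(substitute(expr))
  streams[[as.character(id)]] <- get(".Random.seed", envir = globalenv())
  list(streams = streams, value = val)
}

#' Run a MEMMI simulation on a toy system
#'
#' Multi-replica Langevin dynamics (BAOAB splitting) under the combined
#' energy: toy prior + metainference density restraint (with bias-weighted
#' ensemble averaging of the forward-model overlaps) + the shared
#' parallel-bias well-tempered potential.  Systematic errors are
#' Monte-Carlo-sampled at every restraint refresh, finite-ensemble errors
#' estimated on the fly, neighbor lists rebuilt, and hills deposited and
#' shared across walkers at their strides.  With an empty CV list the run
#' reduces exactly to the unaccelerated density-restrained scheme (all
#' unbiasing weights 1); with no data map it reduces to plain parallel-bias
#' metadynamics.  Fully reproducible per seed.
#'
#' @param system a [ToySystem-class].
#' @param data the data [GaussianMixtureMap-class], or `NULL` for no
#'   restraint.
#' @param cvs list of CV specifications; entries flagged by `biasMask =
#'   FALSE` are recorded but not biased.
#' @param cfg a [memmiConfig()] list.
#' @param params forward-model parameters.
#' @param biasMask logical vector over `cvs`; `FALSE` entries are monitor
#'   CVs.
#' @param logFile optional path for a run log (seeds, strides, acceptance
#'   rates, hill counts, walker syncs).
#' @return a [MemmiTrajectory-class].
#' @export
runMEMMI <- function(system, data = NULL, cvs = list(), cfg = memmiConfig(),
                     params = forwardModelParams(),
                     biasMask = rep(TRUE, length(cvs)), logFile = NULL) {
  stopifnot(is(system, "ToySystem"))
  N <- nrow(system@meta)
  R <- cfg$nReplicas
  kBT <- .kB * cfg$temperature
  m <- system@masses
  nCV <- length(cvs)
  biasedIdx <- which(biasMask)
  haveBias <- length(biasedIdx) > 0
  haveData <- !is.null(data)

  bias <- biasState(cvs[biasedIdx], temperature = cfg$temperature,
                    gamma = cfg$gamma, h0 = cfg$h0, stride = cfg$hillStride,
                    widthFloor = cfg$widthFloor, widthCap = cfg$widthCap)

  if (haveData) {
    sel <- .fm_atoms(toyConformation(system), params)
    pre <- .overlap_pre(data, params$sigma)
    ovDD <- selfOverlap(data)
    med <- stats::median(ovDD)
    err <- errorState(R, nComponents(data),
                      sigmaMin = cfg$sigmaMinFactor * med,
                      sigmaMax = cfg$sigmaMaxFactor * med,
                      mcStep = cfg$mcStep, sigmaSEM = cfg$sigmaSEMConstant)
    ovHist <- matrix(NA_real_, 0, nComponents(data))
  } else {
    sel <- NULL; err <- NULL; ovDD <- NULL
  }

  streams <- .stream_new(cfg$seed, c(0, seq_len(R)))
  X <- vector("list", R); V <- vector("list", R)
  for (r in seq_len(R)) {
    d <- .stream_draw(streams, r, {
      x0 <- system@refCoords + 0.01 * matrix(stats::rnorm(3 * N), N, 3)
      v0 <- matrix(stats::rnorm(3 * N, 0, sqrt(kBT / m)), N, 3)
      list(x0, v0)
    })
    streams <- d$streams
    X[[r]] <- d$value[[1]]; V[[r]] <- d$value[[2]]
  }

  c1 <- exp(-cfg$friction * cfg$dt)
  c2 <- sqrt((1 - c1^2) * kBT / m)

  # per-replica Gaussian noise drawn in blocks to amortise stream switching
  noiseBlock <- 512L
  noiseBuf <- vector("list", R)
  noisePos <- rep(noiseBlock, R)
  draw_noise <- function(r) {
    if (noisePos[r] >= noiseBlock) {
      d <- .stream_draw(streams, r,
                        array(stats::rnorm(3 * N * noiseBlock),
                              c(N, 3, noiseBlock)))
      streams <<- d$streams
      noiseBuf[[r]] <<- d$value
      noisePos[r] <<- 0L
    }
    noisePos[r] <<- noisePos[r] + 1L
    noiseBuf[[r]][, , noisePos[r]]
  }

  nlSets <- NULL
  rebuild_nl <- function() {
    lapply(seq_len(R), function(r)
      cpp_nl_build(X[[r]][sel$idx, , drop = FALSE], sel$w, pre$dmu, pre$dinv,
                   pre$dnc, pre$dw, ovDD, cfg$nlCutoff))
  }
  if (haveData) nlSets <- rebuild_nl()

  cv_val <- matrix(0, R, nCV)
  vpb <- numeric(R)
  Fbias <- rep(list(matrix(0, N, 3)), R)
  Frest <- rep(list(matrix(0, N, 3)), R)
  Eprior <- numeric(R)
  Edata <- 0; Eerr <- 0
  ovR <- if (haveData) matrix(0, R, nComponents(data)) else NULL
  accRates <- numeric(0)
  histLen <- max(2L, cfg$hillStride)
  cvRing <- rep(list(matrix(NA_real_, histLen, nCV)), R)
  nSync <- 0L

  hillMat <- .hill_matrices(bias)
  zeroF <- matrix(0, N, 3)
  cvdefs <- lapply(cvs, function(spec) {
    if (spec$kind == "dihedral")
      list(kind = 1L, atoms = spec$atoms)
    else
      list(kind = 2L, g1 = spec$group1, g2 = spec$group2, r0 = spec$r0,
           n = spec$n, m = spec$m)
  })
  eval_cv_bias <- function(r) {
    if (nCV == 0) return(list(vals = numeric(0), force = zeroF, vpb = 0))
    cpp_cv_bias_force(X[[r]], cvdefs, biasedIdx, hillMat, bias@periodic, kBT)
  }

  update_restraint <- function() {
    for (r in seq_len(R))
      ovR[r, ] <<- cpp_overlaps(X[[r]][sel$idx, , drop = FALSE], sel$w,
                                pre$dmu, pre$dinv, pre$dnc, pre$dw, nlSets[[r]])
    w <- if (haveBias) unbiasWeight(vpb, cfg$temperature) else rep(1, R)
    avOv <- ensembleAverageOverlap(ovR, w)
    if (cfg$sigmaSEMMode == "windowed") {
      ovHist <<- rbind(ovHist, colMeans(ovR))
      if (nrow(ovHist) > cfg$sigmaSEMWindow)
        ovHist <<- ovHist[-1, , drop = FALSE]
      if (nrow(ovHist) >= 2)
        err@sigmaSEM <<- suppressMessages(
          updateSigmaSEM(ovHist, cfg$sigmaSEMWindow, cfg$sigmaSEMConstant))
    }
    d <- .stream_draw(streams, 0, .mc_sweep(err, avOv, ovDD, TRUE))
    streams <<- d$streams
    err <<- d$value$state
    accRates <<- c(accRates, d$value$acceptance)
    s2 <- .sigma_eff2(err)
    resid <- matrix(ovDD - avOv, R, length(ovDD), byrow = TRUE)
    prefVec <- kBT * colSums(resid / s2)
    wfrac <- w / sum(w)
    for (r in seq_len(R)) {
      G <- cpp_overlap_weighted_grad(X[[r]][sel$idx, , drop = FALSE], sel$w,
                                     pre$dmu, pre$dinv, pre$dnc, pre$dw,
                                     nlSets[[r]], prefVec * wfrac[r])
      FF <- matrix(0, N, 3); FF[sel$idx, ] <- G
      Frest[[r]] <<- FF
    }
    mi <- metainferenceEnergy(avOv, ovDD, err, cfg$temperature)
    Edata <<- mi$data; Eerr <<- mi$error
  }

  # initial forces
  Ftot <- vector("list", R)
  Fff <- vector("list", R)
  for (r in seq_len(R)) {
    ff <- .toy_ff(system, X[[r]])
    Eprior[r] <- ff$energy
    Fff[[r]] <- ff$forces
    cb <- eval_cv_bias(r)
    cv_val[r, ] <- cb$vals; vpb[r] <- cb$vpb; Fbias[[r]] <- cb$force
  }
  if (haveData) update_restraint()
  for (r in seq_len(R))
    Ftot[[r]] <- Fff[[r]] + Fbias[[r]] + (if (haveData) Frest[[r]] else 0)

  nSave <- length(seq(cfg$saveStride, cfg$nSteps, by = cfg$saveStride))
  repOut <- lapply(seq_len(R), function(r)
    list(coords = array(NA_real_, c(N, 3, nSave)), steps = integer(nSave),
         cv = matrix(NA_real_, nSave, nCV), vpb = numeric(nSave),
         weight = numeric(nSave), energy = matrix(NA_real_, nSave, 5,
           dimnames = list(NULL, c("prior", "data", "error", "kinetic",
                                   "total")))))
  sigmaTrace <- if (haveData) array(NA_real_, c(R, nComponents(data), nSave))
                else array(0, c(R, 0, nSave))
  iSave <- 0L

  for (step in seq_len(cfg$nSteps)) {
    for (r in seq_len(R)) {
      V[[r]] <- V[[r]] + 0.5 * cfg$dt * Ftot[[r]] / m
      X[[r]] <- X[[r]] + 0.5 * cfg$dt * V[[r]]
      if (cfg$friction > 0)
        V[[r]] <- c1 * V[[r]] + c2 * draw_noise(r)
      X[[r]] <- X[[r]] + 0.5 * cfg$dt * V[[r]]
      if (!all(is.finite(X[[r]])))
        stop(sprintf("non-finite coordinates at step %d, replica %d", step, r))
    }

    if (haveData && step %% cfg$neighborStride == 0) nlSets <- rebuild_nl()

    for (r in seq_len(R)) {
      cb <- eval_cv_bias(r)
      cv_val[r, ] <- cb$vals; vpb[r] <- cb$vpb; Fbias[[r]] <- cb$force
      cvRing[[r]][1 + (step - 1) %% histLen, ] <- cb$vals
    }

    if (haveData && step %% cfg$restraintStride == 0) update_restraint()

    if (haveBias && step %% cfg$hillStride == 0) {
      deltas <- vector("list", R)
      for (r in seq_len(R)) {
        hist_r <- cvRing[[r]][stats::complete.cases(cvRing[[r]]), biasedIdx,
                              drop = FALSE]
        deltas[[r]] <- depositHills(cv_val[r, biasedIdx], bias, walker = r,
                                    step = step, cvHistory = hist_r)
      }
      bias <- syncWalkers(deltas)
      hillMat <- .hill_matrices(bias)
      nSync <- nSync + 1L
    }

    for (r in seq_len(R)) {
      ff <- .toy_ff(system, X[[r]])
      Eprior[r] <- ff$energy
      Ftot[[r]] <- ff$forces + Fbias[[r]] + (if (haveData) Frest[[r]] else 0)
      V[[r]] <- V[[r]] + 0.5 * cfg$dt * Ftot[[r]] / m
    }

    if (step %% cfg$saveStride == 0) {
      iSave <- iSave + 1L
      w <- if (haveBias) unbiasWeight(vpb, cfg$temperature) else rep(1, R)
      for (r in seq_len(R)) {
        repOut[[r]]$coords[, , iSave] <- X[[r]]
        repOut[[r]]$steps[iSave] <- step
        repOut[[r]]$cv[iSave, ] <- cv_val[r, ]
        repOut[[r]]$vpb[iSave] <- vpb[r]
        repOut[[r]]$weight[iSave] <- w[r]
        repOut[[r]]$energy[iSave, ] <- c(Eprior[r], Edata, Eerr,
                                         0.5 * sum(m * V[[r]]^2),
                                         Eprior[r] + Edata + Eerr)
      }
      if (haveData) sigmaTrace[, , iSave] <- err@sigmaB
    }
  }

  runLog <- list(seed = cfg$seed,
                 strides = cfg[c("restraintStride", "neighborStride",
                                 "hillStride", "saveStride")],
                 mcAcceptance = if (length(accRates)) mean(accRates) else NA_real_,
                 hillCounts = vapply(bias@hills, nrow, 1L),
                 walkerSyncs = nSync)
  if (!is.null(logFile)) {
    writeLines(c(sprintf("# memmi run log"),
                 sprintf("seed: %d  replicas: %d  steps: %d  dt: %g ps", cfg$seed,
                         R, cfg$nSteps, cfg$dt),
                 sprintf("strides: restraint %d, neighbor %d, hills %d, save %d",
                         cfg$restraintStride, cfg$neighborStride,
                         cfg$hillStride, cfg$saveStride),
                 sprintf("sigma MC mean acceptance: %.3f", runLog$mcAcceptance),
                 sprintf("hills per CV: %s",
                         paste(runLog$hillCounts, collapse = ", ")),
                 sprintf("walker sync events: %d", nSync)), logFile)
  }

  new("MemmiTrajectory", replicas = repOut, sigmaTrace = sigmaTrace,
      errorState = err, biasState = bias, cvs = cvs, system = system,
      dataMap = data, config = cfg,
      log = c(runLog, list(biasMask = biasMask)))
}

#' Paired biased/unbiased run on a symmetric CV pair
#'
#' Runs one simulation in which only the first member of a symmetric CV pair
#' receives metadynamics bias while the second is merely monitored — the
#' controlled comparison behind transition-rate acceleration claims.
#'
#' @param system a [ToySystem-class] with two symmetric CV instances.
#' @param data optional data map.
#' @param cvPair list of two CV specifications (biased, mirror).
#' @param cfg a [memmiConfig()] list.
#' @param ... passed to [runMEMMI()].
#' @return the [MemmiTrajectory-class]; CV column 1 is biased, column 2 the
#'   unbiased mirror.
#' @export
runComparison <- function(system, data = NULL, cvPair, cfg = memmiConfig(),
                          ...) {
  stopifnot(length(cvPair) == 2)
  runMEMMI(system, data = data, cvs = cvPair, cfg = cfg,
           biasMask = c(TRUE, FALSE), ...)
}
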