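#' Construct a metainference error state
#'
#' Default bounds are scale-free in the data self-overlap:
#' `sigmaMin = 1e-4 * median(ov_DD)` and `sigmaMax = 10 * median(ov_DD)`.
#' `sigmaB` starts at the geometric mean of the bounds unless given.
#'
#' @param nReplicas,nData dimensions of the `sigmaB` matrix.
#' @param ovDD data self-overlap vector used to set default bounds.
#' @param sigmaMin,sigmaMax bounds on `sigmaB`.
#' @param sigmaB optional initial matrix (recycled scalar allowed).
#' @param sigmaSEM initial per-data-point ensemble error (default 0).
#' @param mcStep multiplicative log-space Monte-Carlo step.
#' @return an [ErrorState-class].
#' @export
errorState <- function(nReplicas, nData, ovDD = NULL,
                       sigmaMin = NULL, sigmaMax = NULL,
                       sigmaB = NULL, sigmaSEM = 0, mcStep = 0.05) {
  if (is.null(sigmaMin) || is.null(sigmaMax)) {
    if (is.null(ovDD)) stop("give ovDD or explicit sigma bounds")
    med <- stats::median(ovDD)
    if (is.null(sigmaMin)) sigmaMin <- 1e-4 * med
    if (is.null(sigmaMax)) sigmaMax <- 10 * med
  }
  if (is.null(sigmaB)) sigmaB <- sqrt(sigmaMin * sigmaMax)
  sigmaB <- matrix(sigmaB, nReplicas, nData)
  new("ErrorState", sigmaB = sigmaB,
      sigmaSEM = rep_len(as.numeric(sigmaSEM), nData),
      sigmaMin = sigmaMin, sigmaMax = sigmaMax, mcStep = mcStep)
}

#' Weighted ensemble average of per-replica overlaps
#'
#' `<ov>_i = sum_r w_r ov_{r,i} / sum_r w_r` — the bias-unbiased replica
#' average that replaces the arithmetic mean once walkers carry different
#' bias potentials.
#'
#' @param perReplicaOv replicas x data-points overlap matrix.
#' @param weights per-replica unbiasing weights (>= 0, at least one > 0).
#' @return averaged overlap vector.
#' @export
ensembleAverageOverlap <- function(perReplicaOv, weights) {
  perReplicaOv <- rbind(perReplicaOv)
  if (length(weights) != nrow(perReplicaOv))
    stop("one weight per replica required")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be >= 0 with at least one positive entry")
  as.numeric(crossprod(weights, perReplicaOv) / sum(weights))
}

# effective variance per (replica, data point)
.sigma_eff2 <- function(err) {
  sweep(err@sigmaB^2, 2, err@sigmaSEM^2, "+")
}

#' Metainference energy of the data and error terms
#'
#' For every data point i and replica r the Gaussian data likelihood
#' contributes
#' \eqn{k_B T [ (ov_{DD,i} - <ov>_i)^2 / (2\sigma^2_{r,i}) +
#' \frac12 \log(2\pi\sigma^2_{r,i}) ]} with effective variance
#' \eqn{\sigma^2_{r,i} = (\sigma^B_{r,i})^2 + (\sigma^{SEM}_i)^2}, and the
#' Jeffreys error prior \eqn{p(\sigma^B) \propto 1/\sigma^B} contributes
#' \eqn{E_\sigma = k_B T \sum \log \sigma^B_{r,i}}.  The molecular-mechanics
#' prior is added by the caller.
#'
#' @param avOv ensemble-averaged overlap vector `<ov>`.
#' @param ovDD data self-overlap vector.
#' @param err an [ErrorState-class].
#' @param temperature kelvin.
#' @param priorEnergy optional prior energy to include in the breakdown.
#' @return list with `prior`, `dataPerPoint` (summed over replicas),
#'   `data`, `error` and `total`, all kJ/mol.
#' @export
metainferenceEnergy <- function(avOv, ovDD, err, temperature,
                                priorEnergy = 0) {
  stopifnot(is(err, "ErrorState"), temperature > 0)
  if (length(avOv) != ncol(err@sigmaB) || length(ovDD) != length(avOv))
    stop("overlap vectors and error state are not aligned")
  kBT <- .kB * temperature
  s2 <- .sigma_eff2(err)
  if (any(s2 <= 0)) stop("non-positive effective variance")
  res2 <- (ovDD - avOv)^2
  mism <- sweep(1 / (2 * s2), 2, res2, "*")      # replicas x K
  norm <- 0.5 * log(2 * pi * s2)
  dataPerPoint <- kBT * colSums(mism + norm)
  eSigma <- kBT * sum(log(err@sigmaB))
  total <- priorEnergy + sum(dataPerPoint) + eSigma
  list(prior = priorEnergy, dataPerPoint = dataPerPoint,
       data = sum(dataPerPoint), error = eSigma, total = total)
}

#' Monte-Carlo update of the systematic error parameters
#'
#' One Metropolis sweep over every `sigmaB[r, i]` entry: a multiplicative
#' log-space proposal `sigma' = sigma * exp(u)`, `u ~ U(-step, step)`,
#' accepted with probability `min(1, exp(-dE/kBT))` where `dE` combines the
#' Gaussian data term and the Jeffreys prior energy (whose contribution is
#' cancelled analytically by the Jacobian of the log-space proposal, so the
#' prior is sampled exactly when the likelihood is flat).  Proposals leaving
#' `[sigmaMin, sigmaMax]` are rejected outright.  Deterministic under a
#' fixed seed.
#'
#' @inheritParams metainferenceEnergy
#' @param seed optional integer; when given the sweep runs on a private RNG
#'   stream, otherwise it consumes the caller's stream.
#' @param likelihood logical test hook: `FALSE` removes the data term so the
#'   chain samples the error prior alone.
#' @return list with the updated [ErrorState-class] (`state`) and the sweep
#'   acceptance fraction (`acceptance`).
#' @export
mcUpdateSigma <- function(err, avOv, ovDD, temperature, seed = NULL,
                          likelihood = TRUE) {
  stopifnot(is(err, "ErrorState"))
  run <- function() .mc_sweep(err, avOv, ovDD, likelihood)
  if (is.null(seed)) run() else with_seed(seed, run())
}

.mc_sweep <- function(err, avOv, ovDD, likelihood) {
  sb <- err@sigmaB
  n <- length(sb)
  res2 <- (ovDD - avOv)^2
  res2m <- matrix(res2, nrow(sb), ncol(sb), byrow = TRUE)
  sem2 <- matrix(err@sigmaSEM^2, nrow(sb), ncol(sb), byrow = TRUE)
  prop <- sb * exp(stats::runif(n, -err@mcStep, err@mcStep))
  inb <- prop >= err@sigmaMin & prop <= err@sigmaMax
  s2_old <- sb^2 + sem2
  s2_new <- prop^2 + sem2
  # acceptance exponent in kBT units: the log-space proposal Jacobian
  # (+log sigma'/sigma) cancels the Jeffreys prior energy exactly, so only
  # the likelihood change decides
  dE <- 0
  if (likelihood)
    dE <- res2m / 2 * (1 / s2_new - 1 / s2_old) +
      0.5 * log(s2_new / s2_old)
  acc <- inb & (stats::runif(n) < exp(pmin(0, -dE)))
  sb[acc] <- prop[acc]
  err@sigmaB <- sb
  list(state = err, acceptance = mean(acc))
}

#' Windowed estimate of the finite-ensemble error
#'
#' `sigmaSEM[i]` is the standard error of the replica-mean overlap of data
#' point i over the last `window` history entries (standard deviation divided
#' by the square root of the entries used).  When the history is shorter than
#' the window the whole history is used; with fewer than two entries the
#' configured fallback constant is returned with a notice.
#'
#' @param overlapHistory matrix of replica-mean overlap vectors, one row per
#'   evaluation (most recent last), columns = data points.
#' @param window number of trailing entries to use.
#' @param fallback constant returned when the history is too short.
#' @return per-data-point `sigmaSEM` vector.
#' @export
updateSigmaSEM <- function(overlapHistory, window = 200L, fallback = 0) {
  overlapHistory <- rbind(overlapHistory)
  n <- nrow(overlapHistory)
  if (n < 2) {
    message("overlap history too short for a windowed sigma_SEM; using the fallback constant")
    return(rep(fallback, ncol(overlapHistory)))
  }
  use <- overlapHistory[max(1, n - window + 1):n, , drop = FALSE]
  apply(use, 2, stats::sd) / sqrt(nrow(use))
}

#' Metainference restraint forces
#'
#' Minus the coordinate gradient of the data energy through the overlap
#' vector and the weighted ensemble average: for replica r,
#' \eqn{F = k_B T \frac{w_r}{\sum w} \sum_i \frac{ov_{DD,i}-<ov>_i}
#' {\sigma^2_{eff}} \nabla_x ov_{r,i}} summed over the other replicas'
#' variance channels.  Atoms outside every neighbor set receive zero force.
#'
#' @param conf the replica [Conformation-class].
#' @param params [forwardModelParams()].
#' @param data the data [GaussianMixtureMap-class].
#' @param nl neighbor list (defaults to full).
#' @param err [ErrorState-class].
#' @param avOv ensemble-averaged overlap vector `<ov>`.
#' @param weightFraction this replica's `w_r / sum w` in the average
#'   (1 for a single replica).
#' @param temperature kelvin.
#' @return N x 3 force matrix (kJ/mol/nm) over the included atoms.
#' @export
restraintForce <- function(conf, params, data, nl = NULL, err, avOv,
                           weightFraction = 1, temperature) {
  sel <- .fm_atoms(conf, params)
  X <- conf@coords[sel$idx, , drop = FALSE]
  if (is.null(nl)) nl <- .full_nl(length(sel$idx), data)
  .check_nl(nl, length(sel$idx), data)
  kBT <- .kB * temperature
  s2 <- .sigma_eff2(err)
  ovDD <- nl$ovDD
  pref <- kBT * weightFraction * colSums((matrix(ovDD - avOv, nrow(s2),
          ncol(s2), byrow = TRUE)) / s2)
  pre <- .overlap_pre(data, params$sigma)
  cpp_overlap_weighted_grad(X, sel$w, pre$dmu, pre$dinv, pre$dnc, pre$dw,
                            nl$sets, pref)
}
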