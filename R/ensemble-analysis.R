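#' Weighted ensemble from a trajectory
#'
#' Pools the replicas' saved frames after discarding the initial
#' equilibration fraction and attaches converged unbiasing weights: the
#' final shared bias is evaluated at every frame's CV values, and
#' `w = exp(+V_PB/kBT)` normalised to sum 1.  Runs without bias yield
#' uniform weights.
#'
#' @param traj a [MemmiTrajectory-class].
#' @param equilFraction fraction of initial frames to discard (defaults to
#'   the run configuration).
#' @return a [WeightedEnsemble-class].
#' @export
trajectoryEnsemble <- function(traj, equilFraction = NULL) {
  stopifnot(is(traj, "MemmiTrajectory"))
  eq <- equilFraction %||% traj@config$equilFraction
  biasedIdx <- which(traj@log$biasMask)
  coordsList <- list(); cvList <- list(); prov <- NULL
  for (r in seq_along(traj@replicas)) {
    rep <- traj@replicas[[r]]
    nf <- length(rep$steps)
    keep <- seq_len(nf) > floor(eq * nf)
    coordsList[[r]] <- rep$coords[, , keep, drop = FALSE]
    cvList[[r]] <- rep$cv[keep, , drop = FALSE]
    prov <- rbind(prov, data.frame(replica = r, step = rep$steps[keep]))
  }
  coords <- array(unlist(coordsList),
                  c(dim(coordsList[[1]])[1:2], nrow(prov)))
  cvAll <- do.call(rbind, cvList)
  if (length(biasedIdx) > 0 && sum(vapply(traj@biasState@hills, nrow, 1L)) > 0) {
    # converged-bias estimate: time-averaged V_G per CV, interpolated at the
    # frame CV values and combined by the parallel-bias log-sum-exp
    bias <- traj@biasState
    kBT <- .kB * traj@config$temperature
    expo <- matrix(0, nrow(prov), length(biasedIdx))
    for (jj in seq_along(biasedIdx)) {
      sv <- cvAll[, biasedIdx[jj]]
      grid <- if (bias@periodic[jj]) seq(-pi, pi, length.out = 1001) else
        seq(min(sv) - 1e-9, max(sv) + 1e-9, length.out = 1001)
      vg <- .avg_vg_grid(bias, jj, grid)
      expo[, jj] <- -stats::approx(grid, vg, xout = sv, rule = 2)$y / kBT
    }
    mx <- apply(expo, 1, max)
    vpb <- -kBT * (log(rowSums(exp(expo - mx))) + mx)
    w <- unbiasWeight(vpb, traj@config$temperature)
  } else w <- rep(1, nrow(prov))
  new("WeightedEnsemble", coords = coords, meta = traj@system@meta,
      weights = w / sum(w), provenance = prov)
}

#' Resample an ensemble by its unbiasing weights
#'
#' Multinomial draw of `n` frames with probability proportional to the
#' weights; the returned ensemble is uniform-weight, the form most external
#' analyses expect.  Deterministic per seed.
#'
#' @param ens a [WeightedEnsemble-class] (or [MemmiTrajectory-class], which
#'   is converted first).
#' @param n number of draws.
#' @param seed integer seed.
#' @return a uniform-weight [WeightedEnsemble-class] of `n` frames; the
#'   provenance records the source frames drawn.
#' @export
resampleEnsemble <- function(ens, n, seed = 1L) {
  if (is(ens, "MemmiTrajectory")) ens <- trajectoryEnsemble(ens)
  stopifnot(n >= 1)
  if (all(ens@weights == 0)) stop("all weights are zero")
  idx <- with_seed(seed, sample.int(nFrames(ens), n, replace = TRUE,
                                    prob = ens@weights))
  new("WeightedEnsemble", coords = ens@coords[, , idx, drop = FALSE],
      meta = ens@meta, weights = rep(1 / n, n),
      provenance = ens@provenance[idx, , drop = FALSE])
}

# Kabsch: rotation R (row convention, B %*% R) minimising ||A - B R||
.kabsch <- function(A, B) {
  H <- crossprod(B, A)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

.superpose <- function(ref, X, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(ref))
  w <- w / sum(w)
  cr <- colSums(ref * w); cx <- colSums(X * w)
  A <- sweep(ref, 2, cr); B <- sweep(X, 2, cx)
  R <- .kabsch(A * sqrt(w), B * sqrt(w))
  list(R = R, shift = cr, center = cx)
}

.apply_superpose <- function(X, sp) {
  sweep(sweep(X, 2, sp$center) %*% sp$R, 2, sp$shift, "+")
}

#' RMSD between two frames after optimal superposition
#'
#' Least-squares rigid-body superposition (Kabsch) over the selection,
#' then the root-mean-square deviation over the same selection.
#'
#' @param frameA,frameB N x 3 coordinate matrices (nm) or
#'   [Conformation-class] objects.
#' @param selection atom indices used both for fitting and for the RMSD
#'   (default: all atoms).
#' @return RMSD in nm.
#' @export
rmsdCA <- function(frameA, frameB, selection = NULL) {
  A <- if (is(frameA, "Conformation")) frameA@coords else as.matrix(frameA)
  B <- if (is(frameB, "Conformation")) frameB@coords else as.matrix(frameB)
  if (!all(dim(A) == dim(B))) stop("selections do not match")
  if (is.null(selection)) selection <- seq_len(nrow(A))
  A <- A[selection, , drop = FALSE]; B <- B[selection, , drop = FALSE]
  sp <- .superpose(A, B)
  Bs <- .apply_superpose(B, sp)
  sqrt(mean(rowSums((A - Bs)^2)))
}

#' Residue-wise Lindemann order parameter
#'
#' After weighted rigid-body superposition of every frame onto the
#' weighted-mean structure of the core selection (isolating internal motion
#' from global drift), the per-residue parameter is
#' \eqn{\Delta_L = \sqrt{\langle |x - \bar x|^2 \rangle_{sel}}/a}:
#' the weighted root-mean-square fluctuation of the selected atoms about
#' their weighted mean positions, divided by the reference interatomic
#' length `a`.  Residues with \eqn{\Delta_L < 0.15} are classified
#' solid-like, the melting-criterion threshold; residues whose selection is
#' empty are reported missing, not zero.
#'
#' @param ens a [WeightedEnsemble-class].
#' @param selection `"backbone"` (core beads), `"sidechain"` (tail beads),
#'   or a logical/integer atom selection.
#' @param a reference length, nm (typical nearest-neighbor nonbonded
#'   spacing; mandatory to state — default 0.45 nm).
#' @param fitSelection atoms used for the superposition (default: core
#'   beads when present, else all).
#' @return data.frame with columns resid, deltaL and label
#'   (`solid`/`liquid`); attribute `a` records the reference length.
#' @export
lindemann <- function(ens, selection = "backbone", a = 0.45,
                      fitSelection = NULL) {
  stopifnot(is(ens, "WeightedEnsemble"), a > 0)
  meta <- ens@meta
  selIdx <- if (is.character(selection)) {
    cls <- meta$class %||% rep("core", nrow(meta))
    switch(selection,
           backbone = which(cls == "core"),
           sidechain = which(cls == "tail"),
           stop("unknown selection keyword"))
  } else if (is.logical(selection)) which(selection) else as.integer(selection)
  if (!length(selIdx)) stop("selection is empty")
  if (is.null(fitSelection)) {
    cls <- meta$class %||% rep("core", nrow(meta))
    fitSelection <- if (any(cls == "core")) which(cls == "core")
                    else seq_len(nrow(meta))
  }
  w <- ens@weights
  nf <- nFrames(ens)
  # iterative weighted mean + superposition on the core
  ref <- ens@coords[, , which.max(w)]
  for (iter in 1:3) {
    mean_x <- matrix(0, nrow(meta), 3)
    aligned <- array(0, dim(ens@coords))
    for (f in seq_len(nf)) {
      sp <- .superpose(ref[fitSelection, , drop = FALSE],
                       ens@coords[fitSelection, , f])
      aligned[, , f] <- .apply_superpose(ens@coords[, , f], sp)
      mean_x <- mean_x + w[f] * aligned[, , f]
    }
    ref <- mean_x
  }
  msf <- matrix(0, nrow(meta), 1)
  for (f in seq_len(nf))
    msf <- msf + w[f] * rowSums((aligned[, , f] - ref)^2)
  resids <- sort(unique(meta$resid[selIdx]))
  deltaL <- vapply(resids, function(rr) {
    at <- intersect(selIdx, which(meta$resid == rr))
    if (!length(at)) return(NA_real_)
    sqrt(mean(msf[at, 1])) / a
  }, 0)
  out <- data.frame(resid = resids, deltaL = deltaL,
                    label = ifelse(is.na(deltaL), NA_character_,
                                   ifelse(deltaL < 0.15, "solid", "liquid")))
  attr(out, "a") <- a
  out
}

#' GROMOS conformational clustering
#'
#' Greedy neighbor-count clustering under an RMSD cutoff, weighted by the
#' frame weights: repeatedly take the frame with the largest weighted count
#' of neighbors (frames within `cutoff` RMSD), assign that neighborhood as a
#' cluster with the frame as medoid, remove it, and repeat.  Ties break to
#' the earliest frame index.
#'
#' @param ens a [WeightedEnsemble-class].
#' @param cutoff RMSD cutoff, nm.
#' @param selection atom indices for the RMSD metric (default all).
#' @return list with `membership` (cluster id per frame), `medoids` (frame
#'   indices) and `populations` (weighted, sum 1).
#' @export
gromosCluster <- function(ens, cutoff, selection = NULL) {
  stopifnot(is(ens, "WeightedEnsemble"), cutoff > 0)
  nf <- nFrames(ens)
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1))
    for (j in (i + 1):nf)
      D[i, j] <- D[j, i] <- rmsdCA(ens@coords[, , i], ens@coords[, , j],
                                   selection)
  w <- ens@weights
  membership <- rep(NA_integer_, nf)
  medoids <- integer(0)
  remaining <- seq_len(nf)
  cl <- 0L
  while (length(remaining)) {
    cl <- cl + 1L
    counts <- vapply(remaining, function(i)
      sum(w[remaining][D[i, remaining] <= cutoff]), 0)
    center <- remaining[which.max(counts)]   # which.max: earliest on ties
    members <- remaining[D[center, remaining] <= cutoff]
    membership[members] <- cl
    medoids <- c(medoids, center)
    remaining <- setdiff(remaining, members)
  }
  pop <- vapply(seq_len(cl), function(k) sum(w[membership == k]), 0)
  list(membership = membership, medoids = medoids,
       populations = pop / sum(pop))
}

#' First-half vs second-half convergence report
#'
#' Clusters the first half of the weighted trajectory, assigns second-half
#' frames to the first-half medoids (within the cutoff; new clusters are
#' opened for unassigned frames so populations stay comparable), and
#' reports the weighted populations of both halves together with the
#' maximum absolute population difference — the convergence statistic.
#'
#' @param traj a [MemmiTrajectory-class] (or [WeightedEnsemble-class]).
#' @param cutoff RMSD cutoff, nm.
#' @param selection atoms for the RMSD metric.
#' @return list with `populations` (matrix clusters x 2), `maxDiff` and the
#'   medoid frame indices.
#' @export
convergenceReport <- function(traj, cutoff, selection = NULL) {
  ens <- if (is(traj, "MemmiTrajectory")) trajectoryEnsemble(traj) else traj
  nf <- nFrames(ens)
  half1 <- seq_len(floor(nf / 2))
  half2 <- setdiff(seq_len(nf), half1)
  if (length(half1) < 2 || length(half2) < 2)
    stop("need at least two frames per half")
  sub <- function(idx) {
    w <- ens@weights[idx]
    new("WeightedEnsemble", coords = ens@coords[, , idx, drop = FALSE],
        meta = ens@meta, weights = w / sum(w),
        provenance = ens@provenance[idx, , drop = FALSE])
  }
  e1 <- sub(half1); e2 <- sub(half2)
  cl1 <- gromosCluster(e1, cutoff, selection)
  nMed <- length(cl1$medoids)
  # assign half-2 frames to half-1 medoids, then cluster the leftovers
  memb2 <- rep(NA_integer_, length(half2))
  for (f in seq_along(half2)) {
    d <- vapply(cl1$medoids, function(mm)
      rmsdCA(e2@coords[, , f], e1@coords[, , mm], selection), 0)
    if (min(d) <= cutoff) memb2[f] <- which.min(d)
  }
  extra <- which(is.na(memb2))
  if (length(extra)) {
    clx <- gromosCluster(sub(half2[extra]), cutoff, selection)
    memb2[extra] <- nMed + clx$membership
    nTot <- nMed + max(clx$membership)
  } else nTot <- nMed
  pop <- matrix(0, nTot, 2, dimnames = list(NULL, c("half1", "half2")))
  pop[seq_len(nMed), 1] <- cl1$populations
  w2 <- e2@weights
  for (k in seq_len(nTot)) pop[k, 2] <- sum(w2[memb2 == k])
  list(populations = pop, maxDiff = max(abs(pop[, 1] - pop[, 2])),
       medoids = cl1$medoids)
}

#' Relative data-error profile
#'
#' Per data component i, the time- and replica-averaged sampled error
#' `sigmaB[, i]` divided by the self-overlap `ov_DD,i` — the relative error
#' of each Gaussian data point with respect to its total overlap with the
#' data mixture.  The mean over components summarises the map-wide error
#' level, and the per-component values can be projected onto the component
#' positions for an error map.
#'
#' @param sigmaTrace replicas x data-points x time array of sampled sigmaB
#'   (e.g. the `sigmaTrace` of a [MemmiTrajectory-class]), or a
#'   [MemmiTrajectory-class].
#' @param data the data [GaussianMixtureMap-class].
#' @return list with `relative` (per-component vector), `mean`, and the
#'   component centres (`positions`, nm) for projection.
#' @export
relativeErrorProfile <- function(sigmaTrace, data) {
  if (is(sigmaTrace, "MemmiTrajectory")) sigmaTrace <- sigmaTrace@sigmaTrace
  if (length(dim(sigmaTrace)) != 3 || dim(sigmaTrace)[2] != nComponents(data))
    stop("sigma trace does not match the data map")
  if (dim(sigmaTrace)[3] == 0) stop("empty sigma trace")
  avg <- apply(sigmaTrace, 2, mean)
  rel <- avg / selfOverlap(data)
  list(relative = rel, mean = mean(rel), positions = data@means)
}

#' Count state transitions along a CV trace
#'
#' Partitions the CV range into states by the given boundaries and counts
#' label changes along the trace.  Periodic CVs are wrapped before state
#' assignment.  A hysteresis band around every boundary (default 5% of the
#' trace range) suppresses boundary chatter: a crossing only counts once
#' the trace leaves the band on the other side.
#'
#' @param trace numeric CV time series.
#' @param boundaries increasing boundary values partitioning the range into
#'   >= 2 states.
#' @param periodic wrap the trace onto [-pi, pi) first.
#' @param hysteresis half-width of the dead band around each boundary, in
#'   CV units; `NULL` uses 5% of the observed range.
#' @return integer transition count.
#' @export
transitionCount <- function(trace, boundaries, periodic = FALSE,
                            hysteresis = NULL) {
  if (!length(trace)) stop("empty trace")
  if (!length(boundaries)) stop("need at least one boundary")
  x <- if (periodic) .wrap_pi(trace) else as.numeric(trace)
  if (is.null(hysteresis)) hysteresis <- 0.05 * diff(range(x))
  state_of <- function(v) findInterval(v, sort(boundaries))
  cur <- state_of(x[1])
  count <- 0L
  for (v in x[-1]) {
    s <- state_of(v)
    if (s != cur) {
      # only commit when outside the dead band of the crossed boundary
      if (all(abs(v - boundaries) > hysteresis)) {
        count <- count + 1L
        cur <- s
      }
    }
  }
  count
}
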