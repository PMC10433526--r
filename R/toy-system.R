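#' Build a miniature fibril-like bead system
#'
#' Constructs `nChains` identical bead chains stacked on a regular
#' cross-beta-like lattice.  The first `coreLen` beads of each chain are
#' "core" beads held by stiff bonds, angles, single-well trans dihedrals and
#' inter-chain lattice bonds; the remaining `tailLen` beads form a floppy
#' N-terminal-like tail.  The dihedral at the core-tail junction of every
#' chain is a designated two-well "chi-like" torsion (minima at +-pi/2,
#' barrier `chiBarrier`), the degree of freedom the bias acts on.  A purely
#' repulsive WCA term acts between beads more than three bonds apart.
#' Construction is deterministic per seed (the seed only jitters the
#' reference coordinates slightly to break exact lattice symmetry).
#'
#' @param nChains number of stacked chains (>= 1).
#' @param coreLen core beads per chain (>= 2).
#' @param tailLen tail beads per chain (>= 2).
#' @param seed integer construction seed.
#' @param chiBarrier barrier of the chi-like dihedral, kJ/mol.
#' @param tailDihedralK force constant of the ordinary tail dihedrals.
#' @param tailAngleK force constant of the tail bond angles (kJ/mol/rad^2).
#'   The floppy default gives a disordered fuzzy-coat-like tail; two-state
#'   experiments stiffen it so the tail swings as a defined arm whose in
#'   and out densities are well separated.
#' @param corePosK harmonic position-restraint constant pinning core beads
#'   to the lattice frame (kJ/mol/nm^2); stands in for the map-anchored
#'   fibril core and keeps the assembly from diffusing out of the map frame.
#' @param stackSpacing inter-chain lattice spacing, nm.  The cross-beta-like
#'   default packs chains tightly; two-state experiments that swing tails
#'   out of the chain plane may use a wider stack so the tails of adjacent
#'   chains do not collide.
#' @return a [ToySystem-class]; the reference conformation has every tail
#'   rotated to chi = +pi/2.
#' @export
makeToyFibril <- function(nChains, coreLen, tailLen, seed = 1L,
                          chiBarrier = 15, tailDihedralK = 1.0,
                          tailAngleK = 15, corePosK = 200,
                          stackSpacing = 0.47) {
  stopifnot(nChains >= 1, coreLen >= 2, tailLen >= 2)
  b <- 0.38; theta0 <- 2 * pi / 3          # bond length nm, bead angle
  dx <- b * sqrt(0.75); hy <- b / 2        # zig-zag geometry
  dz <- stackSpacing                       # inter-chain stacking, nm
  L <- coreLen + tailLen
  N <- nChains * L

  coords <- matrix(0, N, 3)
  meta <- data.frame(chain = character(N), resid = integer(N),
                     resname = character(N), name = "CA",
                     element = character(N), class = character(N),
                     stringsAsFactors = FALSE)
  for (ch in seq_len(nChains)) {
    for (t in seq_len(L)) {
      i <- (ch - 1) * L + t
      coords[i, ] <- c((t - 1) * dx, hy * (t %% 2), (ch - 1) * dz)
      core <- t <= coreLen
      meta$chain[i] <- LETTERS[ch]
      meta$resid[i] <- t
      meta$resname[i] <- if (core) "COR" else "TLA"
      meta$element[i] <- if (core) "C" else "N"
      meta$class[i] <- if (core) "core" else "tail"
    }
  }

  kBondCore <- 500; kBondTail <- 300
  kAngCore <- 80; kAngTail <- tailAngleK
  kDihCore <- 30
  kLat <- 400

  bonds <- NULL; angles <- NULL; dih <- NULL; tag <- character(0)
  idx <- function(ch, t) (ch - 1) * L + t
  for (ch in seq_len(nChains)) {
    for (t in seq_len(L - 1)) {
      kb <- if (t < coreLen) kBondCore else kBondTail
      bonds <- rbind(bonds, c(idx(ch, t), idx(ch, t + 1), b, kb))
    }
    for (t in seq_len(L - 2)) {
      ka <- if (t + 2 <= coreLen) kAngCore else kAngTail
      angles <- rbind(angles, c(idx(ch, t), idx(ch, t + 1), idx(ch, t + 2),
                                theta0, ka))
    }
    for (t in seq_len(L - 3)) {
      at <- idx(ch, t:(t + 3))
      if (t + 3 <= coreLen) {          # all-core: stiff trans well
        dih <- rbind(dih, c(at, kDihCore, 1, 0, 1))
        tag <- c(tag, "core")
      } else if (t == coreLen - 1) {   # junction: two-well chi torsion
        dih <- rbind(dih, c(at, chiBarrier / 2, 2, 0, 1))
        tag <- c(tag, "chi")
      } else {
        dih <- rbind(dih, c(at, tailDihedralK, 1, 0, 1))
        tag <- c(tag, "tail")
      }
    }
  }
  for (ch in seq_len(max(nChains - 1, 0))) {
    for (t in seq_len(coreLen)) {
      bonds <- rbind(bonds, c(idx(ch, t), idx(ch + 1, t), dz, kLat))
      if (t < coreLen)                 # diagonal braces against shear
        bonds <- rbind(bonds, c(idx(ch, t), idx(ch + 1, t + 1),
                                sqrt(b^2 + dz^2), kLat / 2))
    }
  }

  # nonbonded pairs: everything more than 3 bonds apart in the bond graph
  A <- matrix(FALSE, N, N)
  for (r in seq_len(nrow(bonds))) A[bonds[r, 1], bonds[r, 2]] <-
      A[bonds[r, 2], bonds[r, 1]] <- TRUE
  reach <- A
  for (hop in 1:2) reach <- reach | ((reach %*% A) > 0)
  pairs <- which(upper.tri(matrix(0, N, N)) & !reach, arr.ind = TRUE)
  storage.mode(pairs) <- "integer"

  coords <- with_seed(seed, coords + 0.005 * matrix(stats::rnorm(3 * N), N, 3))

  chi <- lapply(seq_len(nChains), function(ch)
    idx(ch, (coreLen - 1):(coreLen + 2)))

  sys <- new("ToySystem", meta = meta, masses = rep(1, N),
             bonds = bonds, angles = angles, dihedrals = dih,
             dihedralTag = tag, pairs = pairs, eps = 2.0, sigmaRep = 0.25,
             posK = ifelse(meta$class == "core", corePosK, 0),
             chiAtoms = chi, refCoords = coords)
  sys@refCoords <- setChiAngles(sys, coords, pi / 2)
  sys
}

#' Conformation view of a toy system
#'
#' @param system a [ToySystem-class].
#' @param coords optional coordinates (defaults to the reference).
#' @return a [Conformation-class].
#' @export
toyConformation <- function(system, coords = NULL) {
  conformation(coords %||% system@refCoords, system@meta)
}

# Rodrigues rotation of points about the axis through p along unit u
.rotate_about <- function(X, p, u, alpha) {
  Xc <- sweep(X, 2, p)
  ca <- cos(alpha); sa <- sin(alpha)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) * ca + sa * K + (1 - ca) * (u %o% u)
  sweep(Xc %*% t(R), 2, p, "+")
}

#' Set the chi-like dihedral of every chain
#'
#' Rotates each chain's tail rigidly about its junction bond so the chi
#' dihedral takes the requested value(s); all other internal coordinates are
#' untouched.  Used to build the endpoint conformations of a two-state
#' (tail-in / tail-out) reference mixture.
#'
#' @param system a [ToySystem-class].
#' @param coords starting coordinates (defaults to the reference).
#' @param angles target chi value(s) in rad, recycled over chains.
#' @return the rotated coordinate matrix.
#' @export
setChiAngles <- function(system, coords = NULL, angles) {
  X <- coords %||% system@refCoords
  nChains <- length(system@chiAtoms)
  angles <- rep_len(angles, nChains)
  L <- nrow(system@meta) / nChains
  for (ch in seq_len(nChains)) {
    at <- system@chiAtoms[[ch]]
    cur <- cpp_dihedral_cv(X, at)$value
    delta <- .wrap_pi(angles[ch] - cur)
    axis <- X[at[3], ] - X[at[2], ]
    axis <- axis / sqrt(sum(axis^2))
    movers <- ((ch - 1) * L + 1):(ch * L)
    movers <- movers[movers >= at[3] + 1]
    for (sgn in c(1, -1)) {
      Xt <- X
      Xt[movers, ] <- .rotate_about(X[movers, , drop = FALSE], X[at[3], ],
                                    axis, sgn * delta)
      if (abs(.wrap_pi(cpp_dihedral_cv(Xt, at)$value - angles[ch])) < 1e-9) {
        X <- Xt
        break
      }
    }
  }
  X
}

#' Synthesize a ground-truth data map from a conformational mixture
#'
#' Builds the population-weighted sum of the per-conformation model mixtures
#' — the synthetic analog of an experimental envelope that averages over
#' interconverting states — and renders it on a voxel grid with optional
#' additive Gaussian noise.  The noise-free mixture is the inference target;
#' the noisy voxel map is what a map-fitting step would consume.
#'
#' @param conformations list of [Conformation-class] objects (or coordinate
#'   matrices sharing `meta`).
#' @param populations probability vector (sums to 1 within 1e-8).
#' @param params [forwardModelParams()].
#' @param noiseSd additive voxel noise as a fraction of the peak density.
#' @param thermalSd thermal blurring added in quadrature to the atom kernel
#'   (nm; scalar or per-atom).  Experimental maps average over thermal
#'   motion, so a map emulating a dynamic ensemble must carry the blur that
#'   the simulated ensemble will reproduce; a sharp (thermalSd = 0) map of
#'   rigid endpoints is systematically narrower than any thermalised model.
#' @param grid optional list(origin, spacing, dims) in angstrom; autoscaled
#'   to the mixture's +-4 sigma support when omitted.
#' @param seed RNG seed for the voxel noise.
#' @return list with elements `gmm` (the noise-free data
#'   [GaussianMixtureMap-class]) and `voxel` (the rendered [VoxelMap-class]).
#' @export
synthesizeDataMap <- function(conformations, populations,
                              params = forwardModelParams(), noiseSd = 0,
                              thermalSd = 0, grid = NULL, seed = 1L) {
  if (length(conformations) != length(populations))
    stop("one population per conformation required")
  if (abs(sum(populations) - 1) > 1e-8)
    stop("populations must sum to 1")
  parts <- lapply(seq_along(conformations), function(i) {
    g <- modelGMM(conformations[[i]], params)
    g@weights <- g@weights * populations[i]
    if (any(thermalSd > 0)) {
      add <- rep_len(thermalSd, nComponents(g))^2
      for (k in seq_len(nComponents(g)))
        g@covs[, , k] <- g@covs[, , k] + diag(3) * add[k]
    }
    g
  })
  gmm <- gmmMap(unlist(lapply(parts, componentWeights)),
                do.call(rbind, lapply(parts, componentMeans)),
                array(unlist(lapply(parts, componentCovs)),
                      c(3, 3, sum(vapply(parts, nComponents, 1L)))),
                label = "data")
  if (is.null(grid)) {
    pad <- 4 * sqrt(max(apply(gmm@covs, 3, function(S) max(diag(S)))))
    lo <- (apply(gmm@means, 2, min) - pad) * 10    # nm -> A
    hi <- (apply(gmm@means, 2, max) + pad) * 10
    spacing <- c(1.5, 1.5, 1.5)
    dims <- pmax(ceiling((hi - lo) / spacing) + 1, 2)
    grid <- list(origin = lo, spacing = spacing, dims = dims)
  }
  vox <- voxelizeGMM(gmm, grid$origin, grid$spacing, grid$dims)
  if (noiseSd > 0) {
    vox@values <- with_seed(seed, vox@values + array(
      stats::rnorm(length(vox@values), 0, noiseSd * max(vox@values)),
      dim(vox@values)))
  }
  list(gmm = gmm, voxel = vox)
}

#' Synthesize a data map from empirical state densities
#'
#' The ground-truth analog of an experimental map of a dynamic ensemble:
#' each chi state of the toy system is sampled by a short unbiased pilot
#' simulation, every bead's positional density within the state is
#' summarised by its empirical mean and covariance (conditioning each chain
#' on its own chi state), and the data mixture takes one Gaussian per bead
#' and state with weight population x element weight and covariance equal
#' to the atom kernel plus the empirical spread.  A thermalised simulation
#' of the same system at the target populations can then reproduce this
#' map essentially exactly, which is what makes it a usable inference
#' target: the residual error left for the metainference error model is
#' finite-sampling noise, not a systematic model/map mismatch.
#'
#' @param system a [ToySystem-class].
#' @param chiAngles chi value of each state (rad).
#' @param populations state populations (sum 1).
#' @param params [forwardModelParams()].
#' @param nSteps pilot-simulation steps per state.
#' @param seed master seed for the pilots.
#' @param temperature kelvin.
#' @param mode `"fitted"` (default) renders the population-weighted thermal
#'   density of the pilot ensembles on a voxel grid and fits a smooth
#'   Gaussian mixture to it with [fitGMM()] — the exact analog of
#'   expressing an experimental voxel map as a fitted GMM; `"frames"`
#'   places one sharp atom kernel per bead on a subsample of pilot frames;
#'   `"moments"` compresses each bead-state density into a single
#'   broadened Gaussian.
#' @param framesPerState pilot frames per chain kept (frames/fitted modes).
#' @param nFitComponents mixture size of the fitted map.
#' @param gridSpacing voxel edge of the rendered map, angstrom.
#' @return list with `gmm` (the data [GaussianMixtureMap-class]), the state
#'   reference conformations (`states`), the per-state frame counts used
#'   (`framesUsed`), and in fitted mode the rendered `voxel` map and the
#'   fit correlation `fitCor`.
#' @export
empiricalDataMap <- function(system, chiAngles, populations,
                             params = forwardModelParams(), nSteps = 40000L,
                             seed = 1L, temperature = 300,
                             mode = c("fitted", "frames", "moments"),
                             framesPerState = 40L, nFitComponents = 80L,
                             gridSpacing = 1.5) {
  mode <- match.arg(mode)
  stopifnot(length(chiAngles) == length(populations))
  if (abs(sum(populations) - 1) > 1e-8) stop("populations must sum to 1")
  sel <- .fm_atoms(toyConformation(system), params)
  nChains <- length(system@chiAtoms)
  L <- nrow(system@meta) / nChains
  cvs <- lapply(system@chiAtoms, cvDihedral)
  weights <- NULL; means <- NULL; covList <- list()
  states <- list(); used <- integer(0)
  for (s in seq_along(chiAngles)) {
    sys2 <- system
    sys2@refCoords <- setChiAngles(system, angles = chiAngles[s])
    states[[s]] <- conformation(sys2@refCoords, system@meta)
    # hold the pilot in its state: replace the two-well chi term by a
    # harmonic of identical within-well curvature at the target angle
    chiRows <- which(system@dihedralTag == "chi")
    for (cr in chiRows) {
      curv <- system@dihedrals[cr, 5] * system@dihedrals[cr, 6]^2
      sys2@dihedrals[cr, 5:8] <- c(curv, 1, chiAngles[s], 2)
    }
    cfg <- memmiConfig(nReplicas = 1, nSteps = nSteps, dt = 0.004,
                       friction = 5, temperature = temperature,
                       seed = substream_seed(seed, 100 + s),
                       saveStride = 20L)
    traj <- runMEMMI(sys2, NULL, cvs, cfg,
                     biasMask = rep(FALSE, length(cvs)))
    co <- traj@replicas[[1]]$coords
    cv <- traj@replicas[[1]]$cv
    nf <- dim(co)[3]
    eq <- seq_len(nf) > floor(0.2 * nf)
    kw <- numeric(nrow(system@meta))
    kw[sel$idx] <- sel$w
    nUsed <- 0
    for (ch in seq_len(nChains)) {
      inState <- which(abs(.wrap_pi(cv[, ch] - chiAngles[s])) < pi / 2 & eq)
      if (length(inState) < 10)
        stop(sprintf("pilot for state %d left chain %d too quickly", s, ch))
      nUsed <- nUsed + length(inState)
      beads <- intersect(((ch - 1) * L + 1):(ch * L), sel$idx)
      if (mode %in% c("frames", "fitted")) {
        pick <- with_seed(substream_seed(seed, 200 + 10 * s + ch),
                          sample(inState, framesPerState,
                                 replace = length(inState) < framesPerState))
        for (f in pick) {
          weights <- c(weights, populations[s] * kw[beads] / framesPerState)
          means <- rbind(means, co[beads, , f])
          for (b in beads)
            covList[[length(covList) + 1]] <- diag(3) * params$sigma^2
        }
      } else {
        for (b in beads) {
          Xb <- t(co[b, , inState])
          weights <- c(weights, populations[s] * kw[b])
          means <- rbind(means, colMeans(Xb))
          covList[[length(covList) + 1]] <-
            stats::cov(Xb) + diag(3) * params$sigma^2
        }
      }
    }
    used <- c(used, nUsed)
  }
  covs <- array(unlist(covList), c(3, 3, length(covList)))
  gmm <- gmmMap(weights, means, covs, label = "data")
  if (mode != "fitted")
    return(list(gmm = gmm, states = states, framesUsed = used))
  # render the sampled thermal density and express it as a smooth fitted
  # mixture, as one would fit an experimental voxel map
  pad <- 10 * (4 * sqrt(max(apply(gmm@covs, 3, function(S) max(diag(S))))) + 0.15)
  lo <- apply(gmm@means, 2, min) * 10 - pad
  hi <- apply(gmm@means, 2, max) * 10 + pad
  dims <- pmax(ceiling((hi - lo) / gridSpacing) + 1, 2)
  vox <- voxelizeGMM(gmm, lo, gridSpacing, dims)
  fit <- fitGMM(vox, nFitComponents, seed = substream_seed(seed, 300),
                maxIter = 120L)
  fitCor <- mapCorrelation(voxelizeGMM(fit, lo, gridSpacing, dims), vox)
  list(gmm = fit, states = states, framesUsed = used, voxel = vox,
       fitCor = fitCor)
}

# prior (toy force field) energy and forces
.toy_ff <- function(system, X) {
  cpp_ff(X, system@bonds, system@angles, system@dihedrals, system@pairs,
         system@eps, system@sigmaRep, system@posK, system@refCoords)
}
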