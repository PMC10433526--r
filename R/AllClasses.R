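#' @import methods
NULL

# Boltzmann constant, kJ/(mol K); all energies in the package are kJ/mol,
# lengths nm, times ps, masses u (GROMACS-style units).
.kB <- 0.0083144621

.check_spd <- function(S, tol = 0) {
  if (!is.matrix(S) || !all(dim(S) == c(3L, 3L)) || !all(is.finite(S)))
    return("covariance must be a finite 3x3 matrix")
  if (max(abs(S - t(S))) > 1e-9 * max(1, max(abs(S))))
    return("covariance must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= tol)) return("covariance must be positive-definite")
  NULL
}

#' Single anisotropic 3-D Gaussian density component
#'
#' A weighted normalised Gaussian \eqn{\omega\,N(x; \mu, \Sigma)} — the atom
#' of both data-side and model-side density mixtures.  The weight carries the
#' density integral of the component; the mean is in nm and the covariance in
#' nm^2.
#'
#' @slot weight positive scalar scale factor (density integral).
#' @slot mean numeric length-3 centre, nm.
#' @slot cov symmetric positive-definite 3x3 covariance, nm^2.
#' @export
setClass("GaussianComponent",
  representation(weight = "numeric", mean = "numeric", cov = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@weight) != 1 || !is.finite(object@weight) || object@weight <= 0)
      msg <- c(msg, "weight must be a single positive number")
    if (length(object@mean) != 3 || !all(is.finite(object@mean)))
      msg <- c(msg, "mean must be a finite 3-vector")
    m <- .check_spd(object@cov)
    if (!is.null(m)) msg <- c(msg, m)
    if (length(msg)) msg else TRUE
  })

#' Gaussian mixture representation of a density map
#'
#' An ordered set of [GaussianComponent-class] terms; index `i` identifies a
#' data point throughout the package (overlaps, errors, data-error maps), so
#' component order is part of the object's identity.
#'
#' @slot weights numeric vector of component weights (> 0).
#' @slot means K x 3 matrix of component centres, nm.
#' @slot covs 3 x 3 x K array of component covariances, nm^2.
#' @slot label either `"data"` or `"model"`.
#' @export
setClass("GaussianMixtureMap",
  representation(weights = "numeric", means = "matrix", covs = "array",
                 label = "character"),
  validity = function(object) {
    K <- length(object@weights)
    if (K < 1) return("a mixture needs at least one component")
    if (any(!is.finite(object@weights)) || any(object@weights <= 0))
      return("all weights must be positive and finite")
    if (!all(dim(object@means) == c(K, 3L)) || !all(is.finite(object@means)))
      return("means must be a finite K x 3 matrix")
    if (length(dim(object@covs)) != 3 || !all(dim(object@covs) == c(3L, 3L, K)))
      return("covs must be a 3 x 3 x K array")
    for (i in seq_len(K)) {
      m <- .check_spd(object@covs[, , i])
      if (!is.null(m)) return(sprintf("component %d: %s", i, m))
    }
    if (!object@label %in% c("data", "model"))
      return("label must be 'data' or 'model'")
    TRUE
  })

#' Density values on a regular voxel grid
#'
#' Container for EMD-style maps.  File I/O (MRC/CCP4) is in angstrom; all
#' Gaussian-mixture math in the package is in nm (conversion exactly x 0.1).
#'
#' @slot origin numeric(3), position of the centre of voxel (1,1,1), angstrom.
#' @slot spacing numeric(3), voxel edge lengths, angstrom (> 0).
#' @slot values numeric array of density values, dim = grid dims.
#' @export
setClass("VoxelMap",
  representation(origin = "numeric", spacing = "numeric", values = "array"),
  validity = function(object) {
    if (length(object@origin) != 3 || !all(is.finite(object@origin)))
      return("origin must be a finite 3-vector")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      return("spacing must be positive on every axis")
    d <- dim(object@values)
    if (length(d) != 3 || any(d < 1)) return("values must be a 3-D array")
    TRUE
  })

#' Atomic (or bead) conformation with per-atom metadata
#'
#' @slot coords N x 3 coordinate matrix, nm.
#' @slot meta data.frame with columns chain, resid, resname, name, element.
#' @export
setClass("Conformation",
  representation(coords = "matrix", meta = "data.frame"),
  validity = function(object) {
    if (!all(is.finite(object@coords)) || ncol(object@coords) != 3)
      return("coords must be a finite N x 3 matrix")
    need <- c("chain", "resid", "resname", "name", "element")
    if (!all(need %in% names(object@meta)))
      return(paste("meta must have columns", paste(need, collapse = ", ")))
    if (nrow(object@meta) != nrow(object@coords))
      return("metadata length must match coordinate count")
    TRUE
  })

#' Metainference error parameters
#'
#' Per-replica, per-data-point systematic error scales `sigmaB` and
#' per-data-point finite-ensemble errors `sigmaSEM`, with the bounds and the
#' log-scale Monte-Carlo step used to sample `sigmaB`.
#'
#' @slot sigmaB replicas x data-points matrix, overlap units.
#' @slot sigmaSEM numeric vector (data points), overlap units, >= 0.
#' @slot sigmaMin,sigmaMax bounds enforced on every `sigmaB` entry.
#' @slot mcStep multiplicative log-space Metropolis step size.
#' @export
setClass("ErrorState",
  representation(sigmaB = "matrix", sigmaSEM = "numeric",
                 sigmaMin = "numeric", sigmaMax = "numeric", mcStep = "numeric"),
  validity = function(object) {
    if (object@sigmaMin <= 0 || object@sigmaMax < object@sigmaMin)
      return("need 0 < sigmaMin <= sigmaMax")
    if (any(object@sigmaB < object@sigmaMin - 1e-15) ||
        any(object@sigmaB > object@sigmaMax + 1e-15))
      return("sigmaB entries must lie in [sigmaMin, sigmaMax]")
    if (length(object@sigmaSEM) != ncol(object@sigmaB))
      return("sigmaSEM length must equal the number of data points")
    if (any(object@sigmaSEM < 0)) return("sigmaSEM must be >= 0")
    if (object@mcStep <= 0) return("mcStep must be positive")
    TRUE
  })

#' Shared parallel-bias metadynamics state
#'
#' Per-CV ordered hill lists shared across walkers, with the bias factor and
#' deposition parameters.  Hills are kept sorted by deposit time; the
#' (walker, step, CV) triple is unique.
#'
#' @slot cvnames character, one name per collective variable.
#' @slot periodic logical, TRUE for dihedral CVs (wrapped on [-pi, pi)).
#' @slot hills list of data.frames (center, width, height, time, walker),
#'   one per CV.
#' @slot gamma well-tempered bias factor (> 1; `Inf` = standard metadynamics).
#' @slot temperature kelvin.
#' @slot h0 initial hill height, kJ/mol.
#' @slot stride deposition stride, steps.
#' @slot widthFloor,widthCap per-CV bounds on the adaptive hill width.
#' @export
setClass("BiasState",
  representation(cvnames = "character", periodic = "logical", hills = "list",
                 gamma = "numeric", temperature = "numeric", h0 = "numeric",
                 stride = "numeric", widthFloor = "numeric", widthCap = "numeric"),
  validity = function(object) {
    M <- length(object@cvnames)
    if (length(object@periodic) != M || length(object@hills) != M ||
        length(object@widthFloor) != M || length(object@widthCap) != M)
      return("per-CV fields must all have one entry per CV")
    if (object@gamma <= 1) return("bias factor gamma must be > 1")
    if (object@h0 < 0) return("h0 must be >= 0")
    if (object@stride < 1) return("stride must be >= 1")
    for (j in seq_len(M)) {
      h <- object@hills[[j]]
      if (nrow(h) == 0) next
      if (any(h$height < 0) || any(h$width <= 0))
        return("hill heights must be >= 0 and widths > 0")
      if (is.unsorted(h$time)) return("hills must be sorted by deposit time")
    }
    TRUE
  })

#' Miniature fibril-like bead system
#'
#' Coarse bead topology standing in for an all-atom fibril: stacked chains
#' whose core beads sit on a regular cross-beta-like lattice held by stiff
#' bonded terms, with floppy N-terminal-tail beads hanging off, one designated
#' multi-well "chi-like" dihedral per chain, and a purely repulsive (WCA)
#' nonbonded term.
#'
#' @slot meta per-bead data.frame (chain, resid, resname, name, element, class).
#' @slot masses numeric, u.
#' @slot bonds matrix (i, j, r0, k).
#' @slot angles matrix (i, j, k, theta0, ktheta).
#' @slot dihedrals matrix (i, j, k, l, kd, mult, phase, type); type 1 cosine,
#'   2 harmonic.
#' @slot dihedralTag character: "core", "tail" or "chi" per dihedral row.
#' @slot pairs integer matrix of non-excluded repulsive pairs.
#' @slot eps,sigmaRep WCA repulsion parameters (kJ/mol, nm).
#' @slot posK per-bead harmonic position-restraint constants (kJ/mol/nm^2;
#'   0 = unrestrained).  Core beads are pinned to the lattice frame, playing
#'   the role of the map-anchored fibril core.
#' @slot chiAtoms list (one per chain) of the 4 atom indices of the chi dihedral.
#' @slot refCoords reference N x 3 coordinates, nm.
#' @export
setClass("ToySystem",
  representation(meta = "data.frame", masses = "numeric", bonds = "matrix",
                 angles = "matrix", dihedrals = "matrix", dihedralTag = "character",
                 pairs = "matrix", eps = "numeric", sigmaRep = "numeric",
                 posK = "numeric", chiAtoms = "list", refCoords = "matrix"),
  validity = function(object) {
    if (length(object@masses) != nrow(object@meta))
      return("one mass per bead required")
    if (length(object@posK) != nrow(object@meta) || any(object@posK < 0))
      return("one non-negative position-restraint constant per bead required")
    if (nrow(object@dihedrals) != length(object@dihedralTag))
      return("one tag per dihedral row required")
    core <- object@dihedrals[object@dihedralTag == "core", 5]
    tail <- object@dihedrals[object@dihedralTag == "tail", 5]
    if (length(core) && length(tail) && min(core) <= max(tail))
      return("core dihedral force constants must exceed tail ones")
    TRUE
  })

#' Multi-replica MEMMI trajectory
#'
#' Per-replica frames (coordinates, CV values, bias potential, instantaneous
#' unbiasing weight, energy breakdown) plus the final error and bias states
#' and the sampled-sigma history needed for data-error maps.
#'
#' @slot replicas list; each element holds coords (N x 3 x F array), steps,
#'   cv (F x M), vpb, weight and energy (F x 5: prior, data, error, kinetic,
#'   total metainference energy).
#' @slot sigmaTrace replicas x data-points x F array of sampled sigmaB.
#' @slot errorState final [ErrorState-class] (or NULL-like empty when no data).
#' @slot biasState final [BiasState-class].
#' @slot cvs list of CV specifications used.
#' @slot system the [ToySystem-class] sampled.
#' @slot dataMap the data [GaussianMixtureMap-class] or NULL.
#' @slot config the run configuration list.
#' @slot log named list of run diagnostics (MC acceptance, hill counts, ...).
#' @export
setClass("MemmiTrajectory",
  representation(replicas = "list", sigmaTrace = "array", errorState = "ANY",
                 biasState = "ANY", cvs = "list", system = "ToySystem",
                 dataMap = "ANY", config = "list", log = "list"),
  validity = function(object) {
    for (rep in object@replicas) {
      if (is.unsorted(rep$steps, strictly = TRUE))
        return("frame steps must be strictly increasing")
      if (any(rep$weight < 0)) return("frame weights must be >= 0")
    }
    TRUE
  })

#' Trajectory frames paired with normalised unbiasing weights
#'
#' The object every ensemble analysis consumes: conformations with weights
#' that sum to one, plus frame provenance (replica, step).
#'
#' @slot coords N x 3 x F array of frame coordinates, nm.
#' @slot meta shared per-atom metadata data.frame.
#' @slot weights numeric length F, >= 0, sum 1.
#' @slot provenance data.frame with columns replica, step.
#' @export
setClass("WeightedEnsemble",
  representation(coords = "array", meta = "data.frame", weights = "numeric",
                 provenance = "data.frame"),
  validity = function(object) {
    Fn <- dim(object@coords)[3]
    if (length(object@weights) != Fn)
      return("one weight per frame required")
    if (any(object@weights < 0)) return("weights must be >= 0")
    if (abs(sum(object@weights) - 1) > 1e-10)
      return("weights must sum to 1")
    if (nrow(object@provenance) != Fn)
      return("one provenance row per frame required")
    TRUE
  })

setMethod("show", "GaussianComponent", function(object) {
  cat(sprintf("GaussianComponent: weight %.4g, mean (%.3f, %.3f, %.3f) nm\n",
              object@weight, object@mean[1], object@mean[2], object@mean[3]))
})

setMethod("show", "GaussianMixtureMap", function(object) {
  cat(sprintf("GaussianMixtureMap (%s): %d components, total weight %.4g\n",
              object@label, length(object@weights), sum(object@weights)))
})

setMethod("show", "VoxelMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelMap: %d x %d x %d voxels, spacing (%.2f, %.2f, %.2f) A\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
})

setMethod("show", "Conformation", function(object) {
  cat(sprintf("Conformation: %d atoms, %d chains\n", nrow(object@coords),
              length(unique(object@meta$chain))))
})

setMethod("show", "ErrorState", function(object) {
  cat(sprintf("ErrorState: %d replicas x %d data points, sigmaB in [%.3g, %.3g]\n",
              nrow(object@sigmaB), ncol(object@sigmaB), object@sigmaMin,
              object@sigmaMax))
})

setMethod("show", "BiasState", function(object) {
  nh <- vapply(object@hills, nrow, 1L)
  cat(sprintf("BiasState: %d CVs (%s), %d hills, gamma %.3g, h0 %.3g kJ/mol\n",
              length(object@cvnames), paste(object@cvnames, collapse = ", "),
              sum(nh), object@gamma, object@h0))
})

setMethod("show", "ToySystem", function(object) {
  cat(sprintf("ToySystem: %d beads in %d chains, %d bonds, %d angles, %d dihedrals\n",
              nrow(object@meta), length(unique(object@meta$chain)),
              nrow(object@bonds), nrow(object@angles), nrow(object@dihedrals)))
})

setMethod("show", "MemmiTrajectory", function(object) {
  nf <- if (length(object@replicas)) length(object@replicas[[1]]$steps) else 0L
  cat(sprintf("MemmiTrajectory: %d replicas x %d frames, %d CVs, %s\n",
              length(object@replicas), nf, length(object@cvs),
              if (is.null(object@dataMap)) "no data map" else
                sprintf("%d data components", length(object@dataMap@weights))))
})

setMethod("show", "WeightedEnsemble", function(object) {
  cat(sprintf("WeightedEnsemble: %d frames x %d atoms (effective sample size %.1f)\n",
              dim(object@coords)[3], dim(object@coords)[1],
              1 / sum(object@weights^2)))
})
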