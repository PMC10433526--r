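#' Construct a conformation
#'
#' @param coords N x 3 matrix, nm.
#' @param meta per-atom data.frame with columns chain, resid, resname, name,
#'   element; sensible defaults are filled in when columns are missing.
#' @return a [Conformation-class].
#' @export
conformation <- function(coords, meta = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  defaults <- list(chain = "A", resid = seq_len(n), resname = "BEA",
                   name = "CA", element = "C")
  for (col in names(defaults))
    if (is.null(meta[[col]])) meta[[col]] <- rep_len(defaults[[col]], n)
  new("Conformation", coords = coords, meta = meta)
}

#' Forward-model parameters
#'
#' Parameters of the per-atom Gaussian kernel that turns coordinates into a
#' model density.  Atoms scatter roughly in proportion to their electron
#' count, so the default weight table is the atomic number over the heavy
#' atoms, with hydrogens excluded (their contribution is negligible at the
#' map resolutions of interest).  The kernel width defaults to
#' `0.2 * resolution`, a resolution-scaled isotropic stand-in that is fully
#' configurable.
#'
#' @param resolution nominal map resolution, nm.
#' @param sigma per-atom Gaussian standard deviation, nm.
#' @param weights named per-element weight table (dimensionless, > 0).
#' @param includeHydrogens logical; include H atoms in the model density.
#' @return a validated parameter list.
#' @export
forwardModelParams <- function(resolution = 0.4, sigma = 0.2 * resolution,
                               weights = c(H = 1, C = 6, N = 7, O = 8,
                                           P = 15, S = 16),
                               includeHydrogens = FALSE) {
  stopifnot(sigma > 0, all(weights > 0))
  structure(list(resolution = resolution, sigma = sigma, weights = weights,
                 includeHydrogens = includeHydrogens),
            class = "ForwardModelParams")
}

# atoms retained by the forward model, plus their table weights
.fm_atoms <- function(conf, params) {
  el <- conf@meta$element
  keep <- rep(TRUE, length(el))
  if (!params$includeHydrogens) keep <- el != "H"
  missing <- setdiff(unique(el[keep]), names(params$weights))
  if (length(missing))
    stop("element(s) missing from the forward-model weight table: ",
         paste(missing, collapse = ", "))
  list(idx = which(keep), w = unname(params$weights[el[keep]]))
}

#' Model density from atomic coordinates
#'
#' One isotropic Gaussian per included atom: mean at the atom position,
#' covariance `sigma^2 I`, weight from the per-element table.  Translating
#' the conformation translates every component mean identically.
#'
#' @param conf a [Conformation-class].
#' @param params a [forwardModelParams()] list.
#' @return a `"model"`-labelled [GaussianMixtureMap-class].
#' @export
modelGMM <- function(conf, params = forwardModelParams()) {
  stopifnot(is(conf, "Conformation"))
  sel <- .fm_atoms(conf, params)
  gmmMap(sel$w, conf@coords[sel$idx, , drop = FALSE],
         rep(params$sigma^2, length(sel$idx)), label = "model")
}

#' Neighbor list between model atoms and data components
#'
#' Model atom j is a neighbor of data component i iff the pair overlap
#' exceeds `cutoff` relative to the data self-overlap `ov_DD,i`; normalising
#' by the self-overlap makes the threshold scale-free.  Construction is by
#' exact evaluation of every pair, so it agrees with brute-force filtering by
#' definition.
#'
#' @param model a `"model"` [GaussianMixtureMap-class] (isotropic components).
#' @param data the data [GaussianMixtureMap-class].
#' @param cutoff relative overlap threshold in (0, 1).
#' @param stride rebuild stride in evaluation steps (bookkeeping only here;
#'   honoured by the sampler).
#' @return a `NeighborList`: per-data-component model-atom index vectors plus
#'   the cutoff, stride, and the sizes it was built for.
#' @export
buildNeighborList <- function(model, data, cutoff = 0.01, stride = 100L) {
  stopifnot(cutoff > 0, cutoff < 1, stride >= 1)
  ovDD <- selfOverlap(data)
  cross <- .cross_overlaps(model, data)   # atoms x K
  sets <- lapply(seq_len(ncol(cross)), function(i)
    which(cross[, i] / ovDD[i] > cutoff))
  structure(list(sets = sets, cutoff = cutoff, stride = as.integer(stride),
                 nModel = nComponents(model), nData = nComponents(data),
                 ovDD = ovDD),
            class = "NeighborList")
}

# full neighbor list (every atom against every component)
.full_nl <- function(nModel, data) {
  structure(list(sets = rep(list(seq_len(nModel)), nComponents(data)),
                 cutoff = 0, stride = 1L, nModel = nModel,
                 nData = nComponents(data), ovDD = selfOverlap(data)),
            class = "NeighborList")
}

# Precompute, per data component, the inverse and normalisation of
# (Sigma_i + sigma_atom^2 I) used by every overlap evaluation of a run.
.overlap_pre <- function(data, sigma_atom) {
  K <- nComponents(data)
  dinv <- matrix(0, K, 9)
  dnc <- numeric(K)
  for (i in seq_len(K)) {
    S <- data@covs[, , i] + diag(3) * sigma_atom^2
    dinv[i, ] <- as.numeric(t(solve(S)))     # row-major for the C++ side
    dnc[i] <- 1 / sqrt((2 * pi)^3 * det(S))
  }
  list(dmu = data@means, dinv = dinv, dnc = dnc, dw = data@weights)
}

.check_nl <- function(nl, nAtoms, data) {
  if (nl$nModel != nAtoms || nl$nData != nComponents(data))
    stop("stale neighbor list: sizes do not match model/data")
}

#' Forward-model overlap vector
#'
#' `ov_MD,i`, the overlap of the model density with each data component,
#' restricted to the neighbor sets.  With a full neighbor list and a model
#' identical to the data, this reproduces the data self-overlap exactly.
#'
#' @param conf a [Conformation-class].
#' @param params [forwardModelParams()].
#' @param data the data [GaussianMixtureMap-class].
#' @param nl a neighbor list from [buildNeighborList()] (defaults to full).
#' @return numeric vector of per-data-point overlaps.
#' @export
overlapVector <- function(conf, params, data, nl = NULL) {
  sel <- .fm_atoms(conf, params)
  X <- conf@coords[sel$idx, , drop = FALSE]
  if (is.null(nl)) nl <- .full_nl(length(sel$idx), data)
  .check_nl(nl, length(sel$idx), data)
  pre <- .overlap_pre(data, params$sigma)
  cpp_overlaps(X, sel$w, pre$dmu, pre$dinv, pre$dnc, pre$dw, nl$sets)
}

#' Gradient of one overlap component
#'
#' Analytic gradient of `ov_MD,i` with respect to the positions of the
#' model-building atoms (zero rows for atoms outside the neighbor set).
#'
#' @inheritParams overlapVector
#' @param i data-component index.
#' @return N x 3 gradient matrix over the included atoms, overlap units / nm.
#' @export
overlapGradient <- function(conf, params, data, nl = NULL, i) {
  sel <- .fm_atoms(conf, params)
  X <- conf@coords[sel$idx, , drop = FALSE]
  if (is.null(nl)) nl <- .full_nl(length(sel$idx), data)
  .check_nl(nl, length(sel$idx), data)
  if (i < 1 || i > nComponents(data)) stop("component index out of range")
  pre <- .overlap_pre(data, params$sigma)
  pref <- numeric(nComponents(data)); pref[i] <- 1
  cpp_overlap_weighted_grad(X, sel$w, pre$dmu, pre$dinv, pre$dnc, pre$dw,
                            nl$sets, pref)
}
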