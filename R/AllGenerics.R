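#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("componentWeights", function(x) standardGeneric("componentWeights"))

#' @rdname accessors
#' @export
setGeneric("componentMeans", function(x) standardGeneric("componentMeans"))

#' @rdname accessors
#' @export
setGeneric("componentCovs", function(x) standardGeneric("componentCovs"))

#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("atomMeta", function(x) standardGeneric("atomMeta"))

#' @rdname accessors
#' @export
setGeneric("hills", function(x) standardGeneric("hills"))

#' @rdname accessors
#' @export
setGeneric("frameWeights", function(x) standardGeneric("frameWeights"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Accessors for the core containers
#'
#' Small read-only accessors so downstream code never touches slots directly:
#' `nComponents`, `componentWeights`, `componentMeans`, `componentCovs` for
#' mixtures; `voxelValues` for grids; `coords` and `atomMeta` for
#' conformations, systems and ensembles; `hills` for bias states;
#' `frameWeights` and `nFrames` for weighted ensembles.
#'
#' @param x the object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("nComponents", "GaussianMixtureMap", function(x) length(x@weights))

#' @rdname accessors
#' @export
setMethod("componentWeights", "GaussianMixtureMap", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("componentMeans", "GaussianMixtureMap", function(x) x@means)

#' @rdname accessors
#' @export
setMethod("componentCovs", "GaussianMixtureMap", function(x) x@covs)

#' @rdname accessors
#' @export
setMethod("voxelValues", "VoxelMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("coords", "Conformation", function(x, ...) x@coords)

#' @rdname accessors
#' @export
setMethod("coords", "ToySystem", function(x, ...) x@refCoords)

#' @rdname accessors
#' @export
setMethod("coords", "WeightedEnsemble", function(x, ...) x@coords)

#' @rdname accessors
#' @export
setMethod("atomMeta", "Conformation", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("atomMeta", "ToySystem", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("atomMeta", "WeightedEnsemble", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("hills", "BiasState", function(x) x@hills)

#' @rdname accessors
#' @export
setMethod("frameWeights", "WeightedEnsemble", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("nFrames", "WeightedEnsemble", function(x) dim(x@coords)[3])
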