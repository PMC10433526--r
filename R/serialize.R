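#' Serialize toy systems as YAML
#'
#' Plain-text round trip for [ToySystem-class] objects so command-line runs
#' can pass systems between steps.
#'
#' @param system a [ToySystem-class].
#' @param path YAML file.
#' @export
writeToySystemYAML <- function(system, path) {
  stopifnot(is(system, "ToySystem"))
  mat <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  yaml::write_yaml(list(
    meta = as.list(system@meta),
    masses = as.numeric(system@masses),
    bonds = mat(system@bonds), angles = mat(system@angles),
    dihedrals = mat(system@dihedrals),
    dihedralTag = as.list(system@dihedralTag),
    pairs = mat(system@pairs),
    eps = system@eps, sigmaRep = system@sigmaRep,
    posK = as.numeric(system@posK),
    chiAtoms = lapply(system@chiAtoms, as.integer),
    refCoords = mat(system@refCoords)), path)
  invisible(path)
}

#' @rdname writeToySystemYAML
#' @export
readToySystemYAML <- function(path) {
  y <- yaml::read_yaml(path)
  mat <- function(l, nc) {
    if (length(l) == 0) return(matrix(0, 0, nc))
    do.call(rbind, lapply(l, as.numeric))
  }
  pairs <- mat(y$pairs, 2)
  storage.mode(pairs) <- "integer"
  new("ToySystem",
      meta = as.data.frame(y$meta, stringsAsFactors = FALSE),
      masses = as.numeric(y$masses),
      bonds = mat(y$bonds, 4), angles = mat(y$angles, 5),
      dihedrals = mat(y$dihedrals, 8),
      dihedralTag = as.character(unlist(y$dihedralTag)),
      pairs = pairs, eps = y$eps, sigmaRep = y$sigmaRep,
      posK = as.numeric(y$posK),
      chiAtoms = lapply(y$chiAtoms, as.integer),
      refCoords = mat(y$refCoords, 3))
}
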