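#' Read a conformation from a PDB file
#'
#' Thin wrapper around bio3d's PDB parser; coordinates are converted from
#' angstrom to the package-internal nm.
#'
#' @param path PDB file.
#' @return a [Conformation-class].
#' @export
readPDBConformation <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  el <- at$elesy
  el[is.na(el) | el == ""] <- substr(trimws(at$elety[is.na(el) | el == ""]), 1, 1)
  conformation(cbind(at$x, at$y, at$z) * 0.1,
               data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                          resid = at$resno, resname = at$resid,
                          name = at$elety, element = trimws(el)))
}

#' Write a conformation (or toy system) as a pseudo-PDB
#'
#' Beads are exported as CA pseudo-atoms so standard structure viewers can
#' display toy systems.  Coordinates are written in angstrom.
#'
#' @param conf a [Conformation-class] (or [ToySystem-class], whose reference
#'   coordinates are used).
#' @param path output file.
#' @export
writePDBConformation <- function(conf, path) {
  if (is(conf, "ToySystem")) conf <- toyConformation(conf)
  X <- conf@coords * 10
  m <- conf@meta
  bio3d::write.pdb(file = path, xyz = as.numeric(t(X)),
                   type = rep("ATOM", nrow(X)),
                   resno = m$resid, chain = m$chain,
                   resid = m$resname, elety = m$name,
                   elesy = m$element)
  invisible(path)
}

#' Export hills in a PLUMED-style text table
#'
#' One row per hill: time (deposit step), centre, width, height and the
#' bias factor, per CV, tab-separated with a commented header.
#'
#' @param bias a [BiasState-class].
#' @param path output file.
#' @export
writeHills <- function(bias, path) {
  stopifnot(is(bias, "BiasState"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv center width height biasf walker", con)
  for (j in seq_along(bias@cvnames)) {
    h <- bias@hills[[j]]
    if (!nrow(h)) next
    writeLines(sprintf("%g\t%s\t%.10g\t%.10g\t%.10g\t%g\t%d",
                       h$time, bias@cvnames[j], h$center, h$width, h$height,
                       bias@gamma, h$walker), con)
  }
  invisible(path)
}

#' Export the per-frame weights table
#'
#' Tab-separated rows (step, replica, V_PB, weight) with a commented
#' header — the record from which unbiased ensemble averages are rebuilt.
#'
#' @param traj a [MemmiTrajectory-class].
#' @param path output file.
#' @export
writeWeightsTable <- function(traj, path) {
  stopifnot(is(traj, "MemmiTrajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS step replica vpb weight", con)
  for (r in seq_along(traj@replicas)) {
    rp <- traj@replicas[[r]]
    writeLines(sprintf("%d\t%d\t%.10g\t%.10g", rp$steps, r, rp$vpb,
                       rp$weight), con)
  }
  invisible(path)
}
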