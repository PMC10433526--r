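#' Collective-variable specifications
#'
#' Two CV kinds are supported: a signed torsion angle over four atoms
#' (periodic on `[-pi, pi)`) and a coordination number between two atom
#' groups using the rational switching function
#' \eqn{s(r) = (1-(r/r_0)^n)/(1-(r/r_0)^m)}, whose `r = r0` limit `n/m` is
#' taken exactly.
#'
#' @param atoms integer vector of the four torsion atoms.
#' @param name CV name used in outputs.
#' @return a CV specification list.
#' @export
cvDihedral <- function(atoms, name = paste0("chi_", atoms[1])) {
  atoms <- as.integer(atoms)
  stopifnot(length(atoms) == 4)
  structure(list(kind = "dihedral", atoms = atoms, periodic = TRUE,
                 name = name), class = "CVSpec")
}

#' @param group1,group2 atom-index groups for the coordination number.
#' @param r0 switching radius, nm.
#' @param n,m switching exponents (n < m).
#' @rdname cvDihedral
#' @export
cvCoordination <- function(group1, group2, r0, n = 6, m = 12,
                           name = "ncontacts") {
  stopifnot(length(group1) >= 1, length(group2) >= 1, r0 > 0, n < m)
  structure(list(kind = "coordination", group1 = as.integer(group1),
                 group2 = as.integer(group2), r0 = r0, n = n, m = m,
                 periodic = FALSE, name = name), class = "CVSpec")
}

#' Evaluate a collective variable
#'
#' @param conf a [Conformation-class] or bare N x 3 coordinate matrix (nm).
#' @param spec a CV specification from [cvDihedral()] or [cvCoordination()].
#' @param gradient logical; also return the dense N x 3 gradient.
#' @return the scalar CV value, or a list `(value, grad)` when
#'   `gradient = TRUE`.  Dihedrals are reported in `[-pi, pi)`.
#' @export
evaluateCV <- function(conf, spec, gradient = FALSE) {
  X <- if (is(conf, "Conformation")) conf@coords else as.matrix(conf)
  if (any(unlist(spec[c("atoms", "group1", "group2")]) > nrow(X)))
    stop("CV atom index out of range")
  res <- if (spec$kind == "dihedral") {
    r <- cpp_dihedral_cv(X, spec$atoms)
    if (gradient) {
      G <- matrix(0, nrow(X), 3)
      G[spec$atoms, ] <- r$grad
      r$grad <- G
    }
    r
  } else {
    cpp_coordination_cv(X, spec$group1, spec$group2, spec$r0, spec$n, spec$m)
  }
  if (gradient) res else res$value
}

#' Construct a shared parallel-bias state
#'
#' Hill heights follow the well-tempered protocol with bias factor `gamma`
#' (default 10; `Inf` gives standard metadynamics) and initial height
#' `h0 = 0.3` kJ/mol.  Hill widths adapt to the depositing walker's recent
#' CV fluctuations, bounded below by the per-CV floor (0.05 rad for
#' dihedrals, 0.1 contacts) and above by a per-CV cap (0.15 rad / 0.5
#' contacts) so that a flattened landscape cannot blow the resolution up.
#'
#' @param cvs list of CV specifications.
#' @param temperature kelvin.
#' @param gamma well-tempered bias factor (> 1).
#' @param h0 initial hill height, kJ/mol.
#' @param stride deposition stride, steps.
#' @param widthFloor,widthCap optional per-CV overrides of the adaptive
#'   width bounds.
#' @return an empty [BiasState-class].
#' @export
biasState <- function(cvs, temperature = 300, gamma = 10, h0 = 0.3,
                      stride = 200L, widthFloor = NULL, widthCap = NULL) {
  periodic <- vapply(cvs, function(s) isTRUE(s$periodic), TRUE)
  if (is.null(widthFloor)) widthFloor <- as.numeric(ifelse(periodic, 0.05, 0.1))
  if (is.null(widthCap)) widthCap <- as.numeric(ifelse(periodic, 0.15, 0.5))
  empty <- data.frame(center = numeric(0), width = numeric(0),
                      height = numeric(0), time = numeric(0),
                      walker = integer(0))
  new("BiasState",
      cvnames = vapply(cvs, `[[`, "", "name"), periodic = periodic,
      hills = rep(list(empty), length(cvs)), gamma = gamma,
      temperature = temperature, h0 = h0, stride = as.numeric(stride),
      widthFloor = rep_len(widthFloor, length(cvs)),
      widthCap = rep_len(widthCap, length(cvs)))
}

.hill_matrices <- function(bias) {
  lapply(bias@hills, function(h) cbind(h$center, h$width, h$height))
}

#' Evaluate the parallel-bias potential
#'
#' \eqn{V_{PB}(s) = -k_B T \log \sum_j \exp(-V_{G_j}(s_j)/k_B T)} where
#' `V_Gj` sums that CV's deposited Gaussians (with periodic wrapping for
#' dihedrals).  With no hills this is the constant `-kBT log N_CV`.
#'
#' @param cvValues numeric vector, one value per CV.
#' @param bias a [BiasState-class].
#' @param derivatives logical; also return `dV_PB/ds` and the per-CV `V_G`.
#' @return `V_PB` in kJ/mol (or a list when `derivatives = TRUE`).
#' @export
evaluateBias <- function(cvValues, bias, derivatives = FALSE) {
  stopifnot(is(bias, "BiasState"))
  if (length(cvValues) != length(bias@cvnames))
    stop("one CV value per CV required")
  kBT <- .kB * bias@temperature
  r <- cpp_bias_eval(as.numeric(cvValues), .hill_matrices(bias),
                     bias@periodic, kBT)
  if (derivatives) r else r$vpb
}

#' Deposit one hill per CV
#'
#' Appends, for every CV, a Gaussian hill at the walker's current CV value
#' with the well-tempered height
#' \eqn{h_0 \exp(-V_{G_j}(s_j) / (k_B T (\gamma-1)))} and a width taken from
#' the walker's recent CV fluctuations (standard deviation over the last
#' deposition interval, clamped to the per-CV floor/cap; the floor is used
#' for the first deposit when no history exists).  Calling off-stride is an
#' error.
#'
#' @param cvValues current CV values of the depositing walker.
#' @param bias the shared [BiasState-class].
#' @param walker integer walker id.
#' @param step current MD step (must be a multiple of the stride).
#' @param cvHistory optional recent CV matrix (rows = steps) for the
#'   adaptive widths.
#' @return the updated [BiasState-class].
#' @export
depositHills <- function(cvValues, bias, walker = 1L, step,
                         cvHistory = NULL) {
  stopifnot(is(bias, "BiasState"))
  if (step %% bias@stride != 0)
    stop("deposit called off-stride (step not a multiple of the deposition stride)")
  kBT <- .kB * bias@temperature
  ev <- cpp_bias_eval(as.numeric(cvValues), .hill_matrices(bias),
                      bias@periodic, kBT)
  for (j in seq_along(cvValues)) {
    w <- if (!is.null(cvHistory) && nrow(rbind(cvHistory)) >= 2) {
      h <- rbind(cvHistory)[, j]
      if (bias@periodic[j]) {
        # circular spread: centre on the current value before dispersion
        d <- .wrap_pi(h - cvValues[j])
        stats::sd(d)
      } else stats::sd(h)
    } else bias@widthFloor[j]
    w <- min(max(w, bias@widthFloor[j]), bias@widthCap[j])
    height <- if (is.finite(bias@gamma))
      bias@h0 * exp(-ev$vg[j] / (kBT * (bias@gamma - 1)))
    else bias@h0
    bias@hills[[j]] <- rbind(bias@hills[[j]],
      data.frame(center = cvValues[j], width = w, height = height,
                 time = step, walker = as.integer(walker)))
  }
  bias
}

.wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Merge bias states from multiple walkers
#'
#' Takes the union of the hill lists, sorted by deposit time (then walker,
#' for a stable order); the merge is order-independent and duplicate
#' (walker, step, CV) hills are dropped.  All walkers subsequently evaluate
#' an identical bias.
#'
#' @param states list of [BiasState-class] objects with identical CV sets.
#' @return the merged [BiasState-class].
#' @export
syncWalkers <- function(states) {
  stopifnot(length(states) >= 1)
  ref <- states[[1]]
  for (s in states[-1]) {
    if (!identical(s@cvnames, ref@cvnames) ||
        !identical(s@periodic, ref@periodic))
      stop("walkers have mismatched CV sets")
  }
  merged <- ref
  for (j in seq_along(ref@cvnames)) {
    all_h <- do.call(rbind, lapply(states, function(s) s@hills[[j]]))
    all_h <- all_h[!duplicated(all_h[, c("walker", "time")]), , drop = FALSE]
    all_h <- all_h[order(all_h$time, all_h$walker), , drop = FALSE]
    rownames(all_h) <- NULL
    merged@hills[[j]] <- all_h
  }
  merged
}

#' Bias forces on the atoms
#'
#' Chain rule through the parallel-bias potential and the CV gradients:
#' \eqn{F = -\sum_j (\partial V_{PB}/\partial s_j) \nabla_x s_j}.
#'
#' @param conf a [Conformation-class] or coordinate matrix.
#' @param cvs list of CV specifications (order matching the bias state).
#' @param bias a [BiasState-class].
#' @return N x 3 force matrix, kJ/mol/nm.
#' @export
biasForce <- function(conf, cvs, bias) {
  X <- if (is(conf, "Conformation")) conf@coords else as.matrix(conf)
  vals <- numeric(length(cvs))
  grads <- vector("list", length(cvs))
  for (j in seq_along(cvs)) {
    r <- evaluateCV(X, cvs[[j]], gradient = TRUE)
    vals[j] <- r$value
    grads[[j]] <- r$grad
  }
  ev <- evaluateBias(vals, bias, derivatives = TRUE)
  FF <- matrix(0, nrow(X), 3)
  for (j in seq_along(cvs))
    FF <- FF - ev$dvds[j] * grads[[j]]
  FF
}

#' Unbiasing weights from the bias potential
#'
#' `w = exp(+V_PB / kBT)`.  Overflow is guarded by shifting very large
#' arguments relative to the batch maximum, which cancels after
#' normalisation.
#'
#' @param vpb bias potential value(s), kJ/mol.
#' @param temperature kelvin.
#' @return weights, same length as `vpb`.
#' @export
unbiasWeight <- function(vpb, temperature) {
  stopifnot(temperature > 0)
  s <- vpb / (.kB * temperature)
  shift <- max(0, max(s) - 500)
  exp(s - shift)
}

# V_G of one CV on a grid, averaged over checkpoints spanning the last
# `fraction` of the deposit history (fraction 0 = final bias only).  The
# late-time ripple of a well-tempered bias averages out under this Cesaro
# mean while the converged profile is untouched.
.avg_vg_grid <- function(bias, cv, grid, fraction = 0.5, nCheckpoints = 20L) {
  h <- bias@hills[[cv]]
  H <- cbind(h$center, h$width, h$height)
  n <- nrow(H)
  if (fraction <= 0 || n < 4)
    return(cpp_vg_grid(as.numeric(grid), H, bias@periodic[cv]))
  ks <- unique(round(seq(max(1, ceiling((1 - fraction) * n)), n,
                         length.out = nCheckpoints)))
  acc <- 0
  for (k in ks)
    acc <- acc + cpp_vg_grid(as.numeric(grid), H[seq_len(k), , drop = FALSE],
                             bias@periodic[cv])
  acc / length(ks)
}

#' Free-energy profile from the accumulated bias
#'
#' The well-tempered estimator \eqn{F(s) = -\frac{\gamma}{\gamma-1} V_G(s)}
#' (or `-V_G` for standard metadynamics), shifted so the minimum over the
#' grid is zero.  By default `V_G` is the time average of the bias over
#' checkpoints spanning the last half of the deposit history, which
#' suppresses the late-time hill ripple without moving the converged
#' profile; `timeAverage = 0` uses the final bias alone.
#'
#' @param bias a [BiasState-class].
#' @param cv CV index.
#' @param grid numeric grid of CV values.
#' @param timeAverage trailing fraction of the deposit history averaged
#'   over.
#' @param nCheckpoints number of checkpoints in the average.
#' @return data.frame with columns `s` and `F` (kJ/mol, min 0).
#' @export
freeEnergyProfile <- function(bias, cv = 1L, grid, timeAverage = 0.5,
                              nCheckpoints = 20L) {
  stopifnot(is(bias, "BiasState"))
  if (nrow(bias@hills[[cv]]) == 0) stop("no hills deposited on this CV")
  vg <- .avg_vg_grid(bias, cv, grid, timeAverage, nCheckpoints)
  fac <- if (is.finite(bias@gamma)) bias@gamma / (bias@gamma - 1) else 1
  FE <- -fac * vg
  data.frame(s = as.numeric(grid), F = FE - min(FE))
}
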