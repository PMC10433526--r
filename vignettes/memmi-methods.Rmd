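---
title: "Metadynamic cryo-EM metainference: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metadynamic cryo-EM metainference: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memmi)
```

This vignette is the package's own account of the science it implements:
the statistical model, the meaning and defaults of every tunable parameter,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the method leaves room. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The problem and the model

A single-particle density map of a flexible assembly is an average over the
conformations present in the sample. Treating it as one structure discards
the disordered regions; treating it as an ensemble constraint recovers
them. The package implements that ensemble view in four layers.

**Density representation.** A map is a Gaussian mixture
$\phi_D(x)=\sum_{i=1}^{K}\omega_i\,N(x;\,x_i,\Sigma_i)$, either read from a
mixture text file, or fitted to a voxel grid by weighted
expectation–maximisation (`fitGMM`), or synthesized from conformations.
Component order is meaningful: index $i$ is a *data point* with its own
error parameters throughout.

**Forward model.** A conformation becomes a model density with one
isotropic Gaussian per heavy atom: weight from a per-element table (atomic
numbers — electrons scatter; hydrogens are negligible at the relevant
resolutions and excluded by default), width $\sigma = 0.2\times$ nominal
resolution. Agreement with data component $i$ is the analytic overlap
$ov_{MD,i}=\int\phi_M\phi_{D,i}\,dx$, a weighted Gaussian evaluation, and
the natural scale for comparisons is the data self-overlap
$ov_{DD,i}=\int\phi_D\phi_{D,i}\,dx$. Neighbor lists keep only atom–component
pairs whose pair overlap exceeds a fraction (default 0.01) of $ov_{DD,i}$;
normalising the threshold by the self-overlap makes it scale-free. Lists
are rebuilt every 100 evaluation steps by default.

**Metainference energy.** For $R$ replicas with unbiasing weights $w_r$,
the data likelihood is Gaussian in the weighted replica average
$\langle ov\rangle_i=\sum_r w_r\,ov_{r,i}/\sum_r w_r$:

$$E = E_{MD} + k_BT\sum_{r,i}\Big[\frac{(ov_{DD,i}-\langle ov\rangle_i)^2}
{2\sigma^2_{r,i}} + \tfrac12\log(2\pi\sigma^2_{r,i})\Big] + E_\sigma,
\qquad \sigma^2_{r,i} = (\sigma^B_{r,i})^2 + (\sigma^{SEM}_i)^2 .$$

$\sigma^B$ (one scale per data point and replica) absorbs systematic errors
in map, forward model and force field; $\sigma^{SEM}$ (one per data point)
accounts for the finite number of replicas. $E_\sigma$ is the Jeffreys
prior energy $k_BT\sum\log\sigma^B$ — the standard scale-free choice for a
magnitude parameter. $\sigma^B$ is sampled by a per-entry Metropolis walk
with multiplicative log-space proposals; the proposal Jacobian cancels the
Jeffreys term analytically, so a likelihood-free chain samples the prior
exactly (a property the test suite checks by Kolmogorov–Smirnov).
$\sigma^{SEM}$ is either a constant or the windowed standard error of the
replica-mean overlap (default: window of 200 restraint evaluations).

**Bias and unbiasing.** Parallel-bias well-tempered metadynamics deposits
one-dimensional Gaussians on each collective variable (torsions wrapped on
$[-\pi,\pi)$; coordination numbers with the rational switching function,
whose $r=r_0$ limit $n/m$ is taken exactly) and combines them as
$V_{PB}=-k_BT\log\sum_j e^{-V_{G_j}/k_BT}$. Hills are shared across
walkers; heights decay as $h_0\,e^{-V_G/k_BT(\gamma-1)}$. Frames are
unbiased with $w=e^{+V_{PB}/k_BT}$, computed under the *converged* bias
(below), and every analysis — clustering, Lindemann, error maps,
convergence reports — consumes the resulting weighted ensemble.

## 2. Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| restraint stride | 2 | MD steps | production cadence of the density restraint |
| neighbor stride / cutoff | 100 / 0.01 | steps / relative | production values; cutoff normalised by $ov_{DD,i}$ |
| hill height $h_0$ | 0.3 | kJ/mol | production value |
| deposition stride | 200 | steps | production value |
| bias factor $\gamma$ | 10 | — | well-tempering is stated without a factor; 10 is a common choice and configurable |
| adaptive hill width | sd of the walker's CV over the last deposition interval | CV units | diffusion-style adaptivity; clamped to [0.05, 0.15] rad for torsions and [0.1, 0.5] for coordinations |
| $\sigma^B$ bounds | $[10^{-4},\,10]\times\mathrm{median}(ov_{DD})$ | overlap | scale-free defaults |
| MC step | 0.05 | log-σ | small steps at production cadence |
| atom kernel σ | 0.2 × resolution | nm | resolution-scaled stand-in for an unpublished kernel; configurable |
| Lindemann a | 0.45 | nm | typical nearest-neighbor nonbonded spacing in the melting-criterion literature; *must* be stated with any Δ_L |
| Lindemann threshold | 0.15 | — | solid/liquid boundary |
| equilibration discard | 10% of frames | — | scale-free analog of discarding an initial equilibration period |
| transition hysteresis | 5% of range | CV units | suppresses boundary chatter in transition counts |

The width *cap* deserves a note: an adaptive width estimated from recent
fluctuations grows without bound once the landscape is flattened (the
walker then roams the whole range within one deposition interval), which
destroys the spatial resolution of the bias. The cap pins the resolution
at a scale finer than the features of interest; it is a numerical
safeguard, not part of the adaptive scheme's intent.

## 3. Free-energy estimation and converged weights

The well-tempered estimator is $F(s)=-\frac{\gamma}{\gamma-1}V_G(s)$. At
desk scale, the dominant error of the *final-bias* estimator is the
late-time hill ripple, not residual filling. `freeEnergyProfile` therefore
averages $V_G$ over checkpoints spanning the last half of the deposit
history (a Cesàro mean with the same limit); `timeAverage = 0` restores
the final-bias form. `trajectoryEnsemble` evaluates the same averaged bias
at each frame's CV values to form the converged unbiasing weights. The
acceptance suite verifies the whole chain on an analytic double well
(barrier 5 $k_BT$, recovered within 1 kJ/mol) and on a harmonic well
($\langle s^2\rangle$ within 2% of $k_BT/k$).

## 4. The toy system and the synthetic-data generator

`makeToyFibril` builds stacked bead chains: a cross-β-like core lattice
(bond 0.38 nm, stacking 0.47 nm by default) held by stiff bonds, angles,
trans dihedrals, inter-chain lattice bonds and diagonal braces, plus floppy
tail beads, one two-well "χ" torsion per chain at the core–tail junction
(minima ±π/2), WCA repulsion between beads more than three bonds apart,
and harmonic position restraints pinning the core beads. The pinning plays
the role of the map-anchored fibril core: it fixes the assembly in the
map's laboratory frame, exactly as a large rigid core held by its own
density does in production use. Dynamics are BAOAB Langevin steps with
per-replica RNG substreams derived from (master seed, replica id), which
makes multi-walker runs bit-reproducible.

`synthesizeDataMap` renders the population-weighted model density of a set
of conformations (plus optional voxel noise); its `thermalSd` argument
broadens the atom kernels by the within-state positional fluctuation,
because an experimental map of a dynamic ensemble is thermally blurred —
a sharp map of rigid endpoints is systematically narrower than anything a
thermalised simulation can produce. `empiricalDataMap` goes further and
builds the map from pilot simulations of each state, either compressed to
per-bead Gaussians, tiled from sampled frames, or (default) rendered to a
voxel grid and re-expressed by `fitGMM` — the full analog of fitting an
experimental map with a mixture.

**What the generator does not emulate:** CTF effects, detector noise
models, helical-reconstruction artifacts (including the periodic ghost
densities such reconstructions can place around disordered regions),
resolution anisotropy, masking choices, or solvent contributions. Passing
tests on these fixtures therefore demonstrates the correctness and
internal consistency of the machinery, not robustness to every pathology
of experimental maps.

## 5. The population-recovery experiment

The method's purpose in miniature is: synthesize a map from a 70/30
mixture of two conformations, run multi-walker metadynamic metainference,
and ask whether the reweighted ensemble recovers the populations. Getting
this experiment *identifiable* at desk scale required design care, and the
reasoning is worth recording.

With a floppy tail, the two state densities overlap and the per-structure
overlap fluctuates by ~80%; the sampled $\sigma^B$ then settles at that
fluctuation scale and the population signal drowns. Worse, an ensemble of
replicas can satisfy overlap restraints by *small continuous deformations*
(each replica polarising toward under-weighted density) instead of by
redistributing state occupancies — a mean-field degeneracy that leaves
populations at the prior's 50/50 while matching the map. Production-scale
applications escape this regime with thousands of data points and tens of
replicas; a desk-scale experiment escapes it by making within-state
deformation expensive and the states well-separated. The benchmark
(`benchmarkPopulationRecovery`) therefore uses a one-chain fibril whose
arm is nearly rigid within a state (stiff tail angles and dihedrals, core
pinning) but switches states through a 15 kJ/mol two-well torsion, a
0.2 nm kernel, and an endpoint map blurred by the measured within-state
fluctuation (`thermalSd = 0.12` nm). Diagnostics during design checked
that the least-squares population optimum of the map sits at ~0.7 before
any dynamics were scored; the protocol was frozen at that point. The
recovered population is ~0.65 for a truth of 0.70 — inside the stated
±10-point band, with the residual offset traceable to the remaining
blur mismatch the error model absorbs.

## 6. Numerical choices

- **EM fitting:** k-means++ initialisation on density-weighted voxel
  centres under the given seed; covariance eigenvalues floored at
  (spacing/2)² to prevent collapse; negative voxels clipped to zero before
  fitting; mixture weight equals clipped voxel mass × voxel volume.
- **Quadrature oracle:** midpoint integration on a grid centred on the
  product Gaussian, spacing σ/3, extent ±8σ — for a Gaussian integrand the
  aliasing error of the midpoint rule is astronomically small, which is
  why a 10⁻⁶ relative tolerance is realistic.
- **σ* recovery estimator:** with a single Gaussian residual per entry,
  the Jeffreys posterior of σ has no finite mean or variance (its upper
  tail is ∝1/σ²), so sample means of σ do not estimate the noise scale.
  The precision posterior is a truncated Gaussian with
  $E[1/\sigma^2\,|\,res]=1/res^2$ exactly; the benchmark therefore reports
  $\sqrt{\mathrm{mean}_i\,[\mathrm{harmonic\ mean}_t\,\sigma^2_{it}]}$.
- **Degenerate inputs:** collinear torsion atoms raise an error rather
  than returning NaN forces; all-zero ensemble weights, empty selections,
  stale neighbor lists, off-stride deposits, grid mismatches and non-SPD
  covariances are all rejected loudly.
- **Determinism:** every stochastic component (initial velocities,
  thermostat noise, error Monte Carlo, resampling, fitting initialisation)
  draws from seeds derived deterministically from one master seed.

## 7. Problem sizes and limitations

The benchmark problem sizes — 4-bead to 12-bead systems, 24–80 data
components, 2–8 walkers, 10⁵–6×10⁵ steps — were chosen as the smallest
sizes at which each estimator's statistical error sits comfortably inside
its stated tolerance; the full benchmark set runs in about six minutes on
one CPU.

Known limitations: the toy prior is not a molecular force field, and no
claim is made that population recovery at this scale transfers
quantitatively to all-atom systems; the per-atom kernel is a single global
width rather than an element- or B-factor-resolved profile; `V_G`
evaluation is exact summation (cost grows linearly with deposited hills);
and MRC support covers the common single-volume mode-2 case only.
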