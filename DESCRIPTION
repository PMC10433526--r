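Package: memmi
Title: Metadynamic Cryo-EM Metainference for Heterogeneous Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Determines conformational ensembles restrained by cryo-EM density
    maps using Bayesian metainference accelerated by parallel-bias well-tempered
    metadynamics with multiple walkers. Density maps are represented as Gaussian
    mixture models and compared to an atomic forward model through analytic
    overlap integrals; systematic and finite-ensemble errors are sampled
    alongside the coordinates. Includes a Langevin toy-system sampler that
    exercises the full restrained-and-biased loop at desk scale, plus an
    ensemble-analysis suite: unbiasing-weight resampling, residue-wise Lindemann
    order parameters, GROMOS conformational clustering, convergence reports,
    per-component data-error maps and collective-variable transition counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
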