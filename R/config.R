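#' Read and write structured run configuration files
#'
#' YAML files with sections `run` (the [memmiConfig()] fields),
#' `forward_model` ([forwardModelParams()] fields) and `cvs` (a list of CV
#' definitions: kind plus atoms or group1/group2/r0/n/m).  Unknown keys are
#' rejected so typos fail loudly.  [writeConfigFile()] echoes the effective
#' configuration, which runs place in their output directory.
#'
#' @param path YAML file.
#' @return `readConfigFile` returns list(cfg, params, cvs).
#' @export
readConfigFile <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(memmiConfig, y$run %||% list())
  fm <- y$forward_model %||% list()
  if (!is.null(fm$weights)) fm$weights <- unlist(fm$weights)
  params <- do.call(forwardModelParams, fm)
  cvs <- lapply(y$cvs %||% list(), function(cv) {
    kind <- cv$kind %||% stop("cv entry without a kind")
    cv$kind <- NULL
    if (kind == "dihedral") do.call(cvDihedral, cv)
    else if (kind == "coordination") do.call(cvCoordination, cv)
    else stop("unknown CV kind: ", kind)
  })
  list(cfg = cfg, params = params, cvs = cvs)
}

#' @param cfg a [memmiConfig()] list.
#' @param params a [forwardModelParams()] list.
#' @param cvs list of CV specifications.
#' @rdname readConfigFile
#' @export
writeConfigFile <- function(path, cfg = memmiConfig(),
                            params = forwardModelParams(), cvs = list()) {
  cvOut <- lapply(cvs, function(cv) {
    out <- unclass(cv)
    out$periodic <- NULL
    out
  })
  yaml::write_yaml(list(run = cfg,
                        forward_model = list(resolution = params$resolution,
                                             sigma = params$sigma,
                                             weights = as.list(params$weights),
                                             includeHydrogens = params$includeHydrogens),
                        cvs = cvOut), path)
  invisible(path)
}
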