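# Experiment configuration: defaults, YAML round-trip, validation, dispatch.

.configDefaults <- function(experiment) {
  common <- list(experiment = experiment, seed = 1L, h = 1)
  extra <- switch(experiment,
    relaxation = list(gridKind = "cartesian2d", blockSize = 10L,
                      gridExtent = c(40L, 40L), trials = 100L,
                      D1 = 1, D2 = 1, D3 = 1),
    slit = list(radius = 10, gridExtent = c(101L, 101L), chi1 = 100, chi2 = 5,
                DS = 50, k = 0.1, Q = 2, Xs = 50, D1 = 1, D2 = 1, D3 = 1,
                horizon = 1000, trials = 100L),
    notch = list(radius = 5, gridExtent = c(51L, 51L), proliferationRate = 1,
                 cellTarget = 1000L, a = 0.01, b = 100, v = 1, hillK = 2,
                 hillH = 2, speedFactor = 1, D1 = 1, D2 = 1, D3 = 1,
                 horizon = 10000),
    tumour = list(gridExtent = c(101L, 101L), blockSize = 5L, horizon = 1000,
                  D1 = 0.01, D2 = 25, D3 = 0.01, lambda = 0.0015,
                  kappaProl = 0.65, rhoProl = 0.125, kappaDeath = 0.55,
                  rhoDeath = 0.125, rhoDeg = 0.01, stopAtNecrosis = FALSE),
    stop(sprintf("configuration error: unknown experiment '%s'", experiment)))
  c(common, extra)
}

#' Default configuration for an experiment
#'
#' Returns the fully populated default configuration for one of the four
#' built-in experiments (`"relaxation"`, `"slit"`, `"notch"`, `"tumour"`),
#' with the reference parameter sets filled in.
#'
#' @param experiment experiment name.
#' @return a named list of class `dlcmConfig`.
#' @export
defaultConfig <- function(experiment = c("relaxation", "slit", "notch", "tumour")) {
  experiment <- match.arg(experiment)
  structure(.configDefaults(experiment), class = "dlcmConfig")
}

.validateConfig <- function(cfg) {
  need <- function(cond, what)
    if (!cond) stop(sprintf("configuration error: %s", what))
  defaults <- .configDefaults(cfg$experiment)
  unknown <- setdiff(names(cfg), names(defaults))
  need(length(unknown) == 0,
       paste("unknown keys:", paste(unknown, collapse = ", ")))
  full <- utils::modifyList(defaults, cfg[names(cfg) != "experiment"])
  num <- function(key) as.numeric(full[[key]])
  need(num("h") > 0, "voxel size h must be positive")
  need(is.numeric(full$seed) && full$seed == round(full$seed), "seed must be an integer")
  for (key in intersect(c("D1", "D2", "D3"), names(full)))
    need(num(key) >= 0, sprintf("%s must be nonnegative", key))
  if (!is.null(full$trials)) need(num("trials") >= 1, "trials must be >= 1")
  if (!is.null(full$horizon)) need(num("horizon") > 0, "horizon must be positive")
  if (!is.null(full$radius)) need(num("radius") > 0, "radius must be positive")
  if (!is.null(full$blockSize)) need(num("blockSize") >= 1, "blockSize must be >= 1")
  need(all(unlist(full$gridExtent) >= 1), "gridExtent must be >= 1 per axis")
  if (cfg$experiment == "tumour") {
    for (key in c("lambda", "rhoProl", "rhoDeath", "rhoDeg"))
      need(num(key) >= 0, sprintf("%s must be nonnegative", key))
    for (key in c("kappaProl", "kappaDeath"))
      need(num(key) >= 0 && num(key) <= 1,
           sprintf("%s must lie in [0, 1] (oxygen is normalised)", key))
  }
  if (cfg$experiment == "notch") {
    for (key in c("a", "b", "v", "hillK", "hillH", "speedFactor",
                  "proliferationRate"))
      need(num(key) > 0, sprintf("%s must be positive", key))
    need(num("cellTarget") >= 1, "cellTarget must be >= 1")
  }
  structure(full, class = "dlcmConfig")
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration, fills unset keys with the experiment's
#' defaults ([defaultConfig()]), rejects unknown keys and out-of-range
#' values, and returns the validated configuration.  `loadConfig` and
#' [writeConfig()] round-trip.
#'
#' @param path YAML file path.
#' @return a `dlcmConfig` list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration error: no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment))
    stop("configuration error: missing required key 'experiment'")
  if (!cfg$experiment %in% c("relaxation", "slit", "notch", "tumour"))
    stop(sprintf("configuration error: unknown experiment '%s'", cfg$experiment))
  .validateConfig(cfg)
}

#' @rdname loadConfig
#' @param config a `dlcmConfig` list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run an experiment from a configuration
#'
#' Dispatches a validated configuration to the matching experiment
#' function.  With `outdir` set, writes a run directory: the echoed
#' configuration (`config.yaml`), the event log / final snapshot CSVs of
#' the last trial, and a summary metrics file.
#'
#' @param config a `dlcmConfig` list (from [loadConfig()] or
#'   [defaultConfig()]).
#' @param outdir optional output directory.
#' @return the experiment result list (invisibly when writing to `outdir`).
#' @export
runExperiment <- function(config, outdir = NULL) {
  cfg <- .validateConfig(unclass(config))
  res <- switch(cfg$experiment,
    relaxation = relaxationExperiment(
      gridKind = cfg$gridKind, blockSize = cfg$blockSize,
      gridExtent = unlist(cfg$gridExtent), h = cfg$h,
      constants = rateConstants(cfg$D1, cfg$D2, cfg$D3),
      trials = cfg$trials, seed = cfg$seed),
    slit = slitExperiment(
      radius = cfg$radius, gridExtent = unlist(cfg$gridExtent), h = cfg$h,
      chi1 = cfg$chi1, chi2 = cfg$chi2, DS = cfg$DS, k = cfg$k, Q = cfg$Q,
      Xs = cfg$Xs, D1 = cfg$D1, D2 = cfg$D2, D3 = cfg$D3,
      horizon = cfg$horizon, trials = cfg$trials, seed = cfg$seed),
    notch = deltaNotchExperiment(
      radius = cfg$radius, gridExtent = unlist(cfg$gridExtent), h = cfg$h,
      proliferationRate = cfg$proliferationRate, cellTarget = cfg$cellTarget,
      params = deltaNotchParams(a = cfg$a, b = cfg$b, v = cfg$v,
                                k = cfg$hillK, h = cfg$hillH,
                                speedFactor = cfg$speedFactor),
      constants = rateConstants(cfg$D1, cfg$D2, cfg$D3),
      horizon = cfg$horizon, seed = cfg$seed),
    tumour = tumourExperiment(
      params = tumourParams(lambda = cfg$lambda, kappaProl = cfg$kappaProl,
                            rhoProl = cfg$rhoProl, kappaDeath = cfg$kappaDeath,
                            rhoDeath = cfg$rhoDeath, rhoDeg = cfg$rhoDeg,
                            D1 = cfg$D1, D2 = cfg$D2, D3 = cfg$D3),
      gridExtent = unlist(cfg$gridExtent), h = cfg$h,
      blockSize = cfg$blockSize, horizon = cfg$horizon, seed = cfg$seed,
      stopAtNecrosis = isTRUE(cfg$stopAtNecrosis)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeConfig(cfg, file.path(outdir, "config.yaml"))
    if (!is.null(res$trajectory)) {
      writeEventLog(eventLog(res$trajectory), file.path(outdir, "events.csv"))
      writeSnapshot(finalState(res$trajectory), res$grid,
                    file.path(outdir, "final_snapshot.csv"))
    } else if (length(res$finalStates)) {
      writeSnapshot(res$finalStates[[length(res$finalStates)]], res$grid,
                    file.path(outdir, "final_snapshot.csv"))
      utils::write.csv(data.frame(voxel = seq_len(nVoxels(res$grid)),
                                  density = as.numeric(res$avgDensity)),
                       file.path(outdir, "avg_density.csv"), row.names = FALSE)
    }
    summ <- list(experiment = cfg$experiment, seed = cfg$seed)
    if (!is.null(res$metrics))
      summ$anisotropy <- res$metrics$anisotropy
    if (!is.null(res$centroidDisplacement))
      summ$centroidDisplacement <- as.numeric(res$centroidDisplacement)
    if (!is.null(res$highNotchFraction))
      summ$highNotchFraction <- res$highNotchFraction
    if (!is.null(res$firstDeathTime))
      summ$firstDeathTime <- res$firstDeathTime
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(summ, file.path(outdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      yaml::write_yaml(summ, file.path(outdir, "metrics.yaml"))
    }
    return(invisible(res))
  }
  res
}
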