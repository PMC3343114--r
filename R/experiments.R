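## ---------------------------------------------------------------------
## Desk-scale experiment drivers.  Each named experiment reproduces one of
## the package's summary tables:
##   fig2: standard unit, capacity and silent fraction vs correlations
##   fig3: coding-level and robustness dependence of capacity / silence
##   fig4: bistable unit vs bistable range, with replica-theory overlay
##   fig5: bistable unit with correlated inputs (simulation only)
## CSV tables are the contract; a JSON manifest records every parameter
## and seed so any table can be reproduced bit for bit.
## ---------------------------------------------------------------------

.experimentDefaults <- list(
  fig2 = list(nInputs = 200L, trials = 10L, maxEpochs = 500L, alphaMax = 5,
              cGrid = c(0, 0.2, 0.4, 0.6, 0.8), cInSlices = c(0, 0.4, 0.8),
              fIn = 0.5, fOut = 0.5, seed = 1L),
  fig3 = list(nInputs = 200L, trials = 10L, maxEpochs = 500L, alphaMax = 6,
              cGrid = c(0, 0.4, 0.8), fOutGrid = c(0.2, 0.5),
              fInGrid = c(0.1, 0.5), kappaGrid = c(0, 1, 2), seed = 1L),
  fig4 = list(nInputs = 200L, trials = 10L, maxEpochs = 500L, alphaMax = 5,
              cOutGrid = c(0, 0.3, 0.6), deltaSGrid = c(0, 0.6, 1.2, 1.8,
                                                        2.4),
              fIn = 0.5, fOut = 0.5, seed = 1L),
  fig5 = list(nInputs = 200L, trials = 10L, maxEpochs = 500L, alphaMax = 6,
              cInGrid = c(0, 0.3, 0.6), cOut = 0.6,
              deltaSGrid = c(0, 0.6, 1.2, 1.8, 2.4), fIn = 0.5, fOut = 0.5,
              seed = 1L))

#' Read and validate an experiment configuration file
#'
#' Configurations are YAML key/value files; keys not understood by the
#' requested experiment raise a validation error listing every offender.
#' The input count key is `nInputs` (a bare `N` would be parsed as a YAML
#' 1.1 boolean).
#'
#' @param name experiment name, one of `"fig2" ... "fig5"`.
#' @param path path to a YAML file, or `NULL` for the shipped defaults.
#' @return named list of configuration values.
#' @export
readExperimentConfig <- function(name, path = NULL) {
  name <- match.arg(name, names(.experimentDefaults))
  cfg <- .experimentDefaults[[name]]
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("invalid config keys for ", name, ": ",
           paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  cfg$nInputs <- as.integer(cfg$nInputs)
  cfg$trials <- as.integer(cfg$trials)
  cfg$maxEpochs <- as.integer(cfg$maxEpochs)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.logLine <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

## capacity + silent fraction at the estimated capacity for one condition
.conditionRow <- function(cIn, cOut, fIn, fOut, kappa, deltaS, rule, cfg,
                          seedOffset) {
  N <- cfg$nInputs
  theta <- 1
  eta <- 0.01 * theta / (N * fIn)
  delta <- deltaSimFromScaled(deltaS, theta, N)
  neuron <- neuronConfig(N, theta = theta, delta = delta, kappa = kappa)
  learner <- learnerConfig(eta = eta, rule = rule, maxEpochs = cfg$maxEpochs)
  est <- estimateCapacity(markovSpec(fIn, cIn), markovSpec(fOut, cOut),
                          neuron, learner, nTrials = cfg$trials,
                          seed = childSeed(cfg$seed, seedOffset),
                          alphaMax = cfg$alphaMax)
  ## silent fraction at the capacity edge, first trial's sequence
  ts <- est@protocol$trialSeeds[1L]
  Pedge <- max(2L, as.integer(round(est@perTrial[1L] * N)))
  seqs <- generateAssociations(markovSpec(fIn, cIn), markovSpec(fOut, cOut),
                               N, Pedge, seed = ts)
  lc <- learner; lc@seed <- childSeed(ts, Pedge)
  tr <- trainPerceptron(seqs, neuron, lc)
  sil <- if (converged(tr))
    as.numeric(silentFraction(weights(tr), eta = eta)) else NA_real_
  data.frame(cIn = cIn, cOut = cOut, fIn = fIn, fOut = fOut, kappa = kappa,
             deltaS = deltaS, rule = rule, N = N,
             alphaMean = est@alpha, alphaSd = est@spread,
             silentFraction = sil, nTrials = est@nTrials,
             budgetHit = any(est@protocol$budgetExhausted))
}

#' Run a named desk-scale experiment
#'
#' Produces the experiment's CSV table(s) under `outDir`, together with a
#' `manifest.json` holding every parameter, seed and the package version,
#' and a plain-text log.  Re-running with the same configuration and seed
#' reproduces the tables bit for bit; the manifest alone suffices to
#' reconstruct the command.
#'
#' @param name `"fig2"`, `"fig3"`, `"fig4"` or `"fig5"`.
#' @param config optional path to a YAML configuration accepted by
#'   [readExperimentConfig()].
#' @param outDir output directory (created if missing).
#' @return invisibly, a named list of the written tables.
#' @export
runExperiment <- function(name, config = NULL, outDir = ".") {
  name <- match.arg(name, names(.experimentDefaults))
  cfg <- readExperimentConfig(name, config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logCon <- file(file.path(outDir, paste0(name, ".log")), "w")
  on.exit(close(logCon))
  .logLine(logCon, "experiment ", name, ": N = ", cfg$nInputs, ", trials = ",
           cfg$trials, ", seed = ", cfg$seed)
  tables <- switch(name,
    fig2 = .runFig2(cfg, logCon),
    fig3 = .runFig3(cfg, logCon),
    fig4 = .runFig4(cfg, logCon),
    fig5 = .runFig5(cfg, logCon))
  for (nm in names(tables)) {
    path <- file.path(outDir, paste0(name, "_", nm, ".csv"))
    write.csv(tables[[nm]], path, row.names = FALSE)
    .logLine(logCon, "wrote ", path)
  }
  manifest <- list(experiment = name, config = cfg,
                   package = "percap",
                   version = as.character(packageVersion("percap")),
                   tables = paste0(name, "_", names(tables), ".csv"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tables)
}

.runFig2 <- function(cfg, logCon) {
  rows <- list(); k <- 0L
  for (cc in cfg$cGrid) {            # diagonal c_in = c_out = c
    k <- k + 1L
    .logLine(logCon, "capacity at c_in = c_out = ", cc)
    rows[[k]] <- .conditionRow(cc, cc, cfg$fIn, cfg$fOut, 0, 0, "standard",
                               cfg, k)
  }
  for (ci in cfg$cInSlices) {        # output-correlation slices
    for (co in cfg$cGrid) {
      k <- k + 1L
      rows[[k]] <- .conditionRow(ci, co, cfg$fIn, cfg$fOut, 0, 0,
                                 "standard", cfg, k)
    }
  }
  list(capacity = do.call(rbind, rows))
}

.runFig3 <- function(cfg, logCon) {
  rows <- list(); k <- 0L
  for (fi in cfg$fInGrid) for (fo in cfg$fOutGrid) for (cc in cfg$cGrid) {
    k <- k + 1L
    rows[[k]] <- .conditionRow(cc, cc, fi, fo, 0, 0, "standard", cfg, k)
  }
  codings <- do.call(rbind, rows)
  rows <- list(); k <- 0L
  for (ka in cfg$kappaGrid) for (cc in cfg$cGrid) {
    k <- k + 1L
    .logLine(logCon, "robustness kappa = ", ka, ", c = ", cc)
    rows[[k]] <- .conditionRow(cc, cc, 0.5, 0.5, ka, 0, "standard", cfg,
                               1000L + k)
  }
  list(codings = codings, robustness = do.call(rbind, rows))
}

.runFig4 <- function(cfg, logCon) {
  rows <- list(); theo <- list(); k <- 0L
  for (co in cfg$cOutGrid) for (ds in cfg$deltaSGrid) {
    k <- k + 1L
    .logLine(logCon, "bistable c_out = ", co, ", deltaS = ", ds)
    rows[[k]] <- .conditionRow(0, co, cfg$fIn, cfg$fOut, 0, ds,
                               "bistable_switching", cfg, k)
    sol <- capacitySolution(scaledParams(deltaS = ds, fOut = cfg$fOut,
                                         cOut = co, fIn = cfg$fIn))
    theo[[k]] <- data.frame(cOut = co, deltaS = ds, alphaTheory = sol@alpha,
                            silentTheory = sol@silentFraction,
                            source = "theory")
  }
  list(capacity = do.call(rbind, rows), theory = do.call(rbind, theo))
}

.runFig5 <- function(cfg, logCon) {
  rows <- list(); k <- 0L
  for (ci in cfg$cInGrid) for (ds in cfg$deltaSGrid) {
    k <- k + 1L
    .logLine(logCon, "bistable c_in = ", ci, ", deltaS = ", ds)
    rows[[k]] <- .conditionRow(ci, cfg$cOut, cfg$fIn, cfg$fOut, 0, ds,
                               "bistable_switching", cfg, k)
  }
  list(capacity = do.call(rbind, rows))
}
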