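## Orchestration of the three analyses over a corpus or generator config.

#' Run configuration for the analysis pipeline
#'
#' Validates and completes a run configuration. A run either reads an
#' observed corpus (\code{fixationPath} + \code{sequencePath}) or generates
#' a synthetic one (\code{generator}, a \linkS4class{GeneratorConfig} or a
#' JSON path; the default packaged configuration when \code{NULL}).
#'
#' @param outDir output directory (created if needed).
#' @param fixationPath,sequencePath optional observed-corpus tables.
#' @param generator optional \linkS4class{GeneratorConfig} or JSON path.
#' @param nDyads,nInteractions,nSequences synthetic corpus dimensions.
#' @param segmentMs segment length (ms).
#' @param lagMinMs,lagMaxMs,lagStepMs lag grid for the alignment analysis.
#' @param dimensions kept ENA dimensions.
#' @param seed integer seed for all randomness of the run.
#' @return A validated list of class \code{"dyadENARunConfig"}.
#' @export
runConfig <- function(outDir = "dyadENA-out", fixationPath = NULL,
                      sequencePath = NULL, generator = NULL, nDyads = 13L,
                      nInteractions = 2L, nSequences = 15L, segmentMs = 50,
                      lagMinMs = -2000, lagMaxMs = 2000, lagStepMs = 50,
                      dimensions = 2L, seed = 1L) {
  if (xor(is.null(fixationPath), is.null(sequencePath)))
    stop("fixationPath and sequencePath must be given together")
  if (is.character(generator)) generator <- readGeneratorConfig(generator)
  if (is.null(generator) && is.null(fixationPath))
    generator <- defaultGeneratorConfig()
  if (!is.null(generator)) stopifnot(methods::is(generator,
                                                 "GeneratorConfig"))
  stopifnot(segmentMs > 0, lagStepMs %% segmentMs == 0,
            lagMinMs <= 0, lagMaxMs >= 0, dimensions >= 1,
            nDyads >= 1, nInteractions >= 1, nSequences >= 1)
  structure(list(outDir = outDir, fixationPath = fixationPath,
                 sequencePath = sequencePath, generator = generator,
                 nDyads = as.integer(nDyads),
                 nInteractions = as.integer(nInteractions),
                 nSequences = as.integer(nSequences), segmentMs = segmentMs,
                 lagMinMs = lagMinMs, lagMaxMs = lagMaxMs,
                 lagStepMs = lagStepMs, dimensions = as.integer(dimensions),
                 seed = as.integer(seed)),
            class = "dyadENARunConfig")
}

.loadCorpus <- function(config) {
  if (!is.null(config$fixationPath))
    readGazeCorpus(config$fixationPath, config$sequencePath)
  else
    generateCorpus(config$generator, nDyads = config$nDyads,
                   nInteractions = config$nInteractions,
                   nSequences = config$nSequences, seed = config$seed)
}

.outFile <- function(config, ...) {
  if (!dir.exists(config$outDir))
    dir.create(config$outDir, recursive = TRUE)
  file.path(config$outDir, ...)
}

.logDefaults <- function(config) {
  message("dyadENA run: segment=", config$segmentMs,
          " ms (midpoint rule, sequence-anchored grid); lag grid ",
          config$lagMinMs, "..", config$lagMaxMs, " by ", config$lagStepMs,
          "; d=", config$dimensions,
          "; centering=grand mean; tie-breaks: smallest-|lag| then positive",
          " (lags), phase order (centroids); seed=", config$seed)
}

#' Run the phase-network analysis
#'
#' Discretises the corpus, accumulates dyad-interaction by phase units,
#' builds the ENA space, and writes the unit table (keys + projections),
#' the per-phase mean networks and centroids, and the phase-space figure.
#'
#' @param config a \code{\link{runConfig}}.
#' @param corpus optional pre-loaded corpus (otherwise loaded/generated
#'   from the config).
#' @return Invisibly: list with \code{space}, \code{units}, \code{summaries}.
#' @export
runAnalysis1 <- function(config, corpus = NULL) {
  .logDefaults(config)
  if (is.null(corpus)) corpus <- .loadCorpus(config)
  coded <- discretize(corpus, config$segmentMs)
  units <- accumulateUnits(coded)
  space <- buildSpace(units, d = config$dimensions)
  ut <- cbind(space@units, as.data.frame(space@projections))
  .writeTable(ut, .outFile(config, "analysis1_units.csv"))
  sums <- meanNetwork(space, units, by = "phase")
  mn <- do.call(rbind, lapply(names(sums), function(p)
    data.frame(phase = p, edge = names(sums[[p]]$meanNetwork),
               weight = unname(sums[[p]]$meanNetwork),
               stringsAsFactors = FALSE)))
  .writeTable(mn, .outFile(config, "analysis1_mean_networks.csv"))
  cen <- do.call(rbind, lapply(names(sums), function(p)
    data.frame(phase = p, t(sums[[p]]$centroid), n = sums[[p]]$n,
               ci1 = sums[[p]]$ciHalfWidth[1], ci2 = sums[[p]]$ciHalfWidth[2],
               stringsAsFactors = FALSE)))
  .writeTable(cen, .outFile(config, "analysis1_centroids.csv"))
  .writeTable(data.frame(code = rownames(space@nodes), space@nodes,
                         constrained = space@nodeConstrained),
              .outFile(config, "analysis1_nodes.csv"))
  grDevices::pdf(.outFile(config, "analysis1_space.pdf"), width = 7,
                 height = 7)
  plotSpace(space, units, main = "phase networks")
  grDevices::dev.off()
  invisible(list(space = space, units = units, summaries = sums))
}

#' Run the lag-alignment analysis
#'
#' Computes alignment curves per phase over the configured lag grid, the
#' optimal-lag summary table, and the lag-shifted Same/Different ENA space;
#' writes curve and summary CSVs plus the two figures.
#'
#' @inheritParams runAnalysis1
#' @return Invisibly: list with \code{curves}, \code{optimal},
#'   \code{shifted}.
#' @export
runAnalysis2 <- function(config, corpus = NULL) {
  .logDefaults(config)
  if (is.null(corpus)) corpus <- .loadCorpus(config)
  coded <- discretize(corpus, config$segmentMs)
  cvs <- alignmentCurves(coded, config$lagMinMs, config$lagMaxMs,
                         config$lagStepMs)
  .writeTable(curves(cvs), .outFile(config, "analysis2_curves.csv"))
  ol <- optimalLag(cvs)
  .writeTable(ol, .outFile(config, "analysis2_optimal_lags.csv"))
  sh <- shiftedENA(coded, stats::setNames(ol$lag_ms, ol$phase),
                   d = config$dimensions)
  ut <- cbind(sh$space@units, as.data.frame(sh$space@projections))
  .writeTable(ut, .outFile(config, "analysis2_units.csv"))
  grDevices::pdf(.outFile(config, "analysis2_alignment.pdf"), width = 7,
                 height = 5)
  plotAlignmentCurves(cvs)
  grDevices::dev.off()
  grDevices::pdf(.outFile(config, "analysis2_space.pdf"), width = 7,
                 height = 7)
  plotSpace(sh$space, sh$units, main = "lag-shifted same/different space")
  grDevices::dev.off()
  invisible(list(curves = cvs, optimal = ol, shifted = sh))
}

#' Run the repair-contrast analysis
#'
#' Builds the repair-stratified space and writes the per-phase contrast
#' table (group means, t, p, Cohen's d), the difference networks, and the
#' stratified-space figure.
#'
#' @inheritParams runAnalysis1
#' @return Invisibly: the \code{\link{repairReport}} result.
#' @export
runAnalysis3 <- function(config, corpus = NULL) {
  .logDefaults(config)
  if (is.null(corpus)) corpus <- .loadCorpus(config)
  coded <- discretize(corpus, config$segmentMs)
  rep_ <- repairReport(corpus, coded = coded, dimension = 2L)
  .writeTable(rep_$contrasts, .outFile(config, "analysis3_contrasts.csv"))
  dn <- attr(rep_$contrasts, "differenceNetworks")
  .writeTable(data.frame(phase = rep_$contrasts$phase, dn,
                         check.names = FALSE),
              .outFile(config, "analysis3_difference_networks.csv"))
  grDevices::pdf(.outFile(config, "analysis3_space.pdf"), width = 7,
                 height = 7)
  plotSpace(rep_$space, rep_$units, main = "repair vs no-repair")
  grDevices::dev.off()
  invisible(rep_)
}

#' Simulate and write a synthetic corpus
#'
#' @param config a \code{\link{runConfig}} with a generator.
#' @return Invisibly, the \linkS4class{GazeCorpus} (tables written to the
#'   output directory).
#' @export
simulateCorpus <- function(config) {
  if (is.null(config$generator)) stop("config has no generator")
  corpus <- .loadCorpus(config)
  writeGazeCorpus(corpus, .outFile(config, "fixations.tsv"),
                  .outFile(config, "sequences.tsv"))
  invisible(corpus)
}

#' Run all three analyses
#'
#' Loads (or generates, seeded) the corpus once and runs the phase-network,
#' lag-alignment and repair analyses in the published order. All outputs
#' are bit-identical across reruns with the same config and seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @return Invisibly: named list of the three analysis results.
#' @export
runAll <- function(config) {
  corpus <- .loadCorpus(config)
  a1 <- runAnalysis1(config, corpus)
  a2 <- runAnalysis2(config, corpus)
  a3 <- runAnalysis3(config, corpus)
  invisible(list(analysis1 = a1, analysis2 = a2, analysis3 = a3))
}
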