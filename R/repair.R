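## Repair vs no-repair contrasts (Analysis 3 analogue).

#' Split units by repair stratum
#'
#' Accumulates dyad-interaction by phase by repair units: each unit counts
#' only the segments of its repair stratum's sequences. Interactions whose
#' stratum contains no sequence simply contribute no unit; all-zero units
#' are dropped with a message.
#'
#' @param x a \linkS4class{CodedSegments} on the \code{"gaze8"} set.
#' @param corpus the \linkS4class{GazeCorpus} carrying the repair flags.
#' @return An \linkS4class{ENAUnitSet} keyed by dyad, interaction, phase
#'   and repair.
#' @export
splitUnits <- function(x, corpus) {
  sq <- sequences(corpus)
  if (!any(sq$repair))
    warning("corpus contains no repair sequences; contrast will be skipped")
  units <- accumulateUnits(x, by = c("dyad_id", "interaction_id", "phase",
                                     "repair"), corpus = corpus)
  if (any(units@units$empty))
    message(sum(units@units$empty), " empty units dropped")
  keep <- !units@units$empty
  methods::new("ENAUnitSet", units = units@units[keep, , drop = FALSE],
               U = units@U[keep, , drop = FALSE],
               nU = units@nU[keep, , drop = FALSE], set = units@set)
}

#' Repair vs no-repair contrast for one phase
#'
#' Computes, inside a shared ENA space holding both strata, the centroid
#' t-test between repair and no-repair units of one phase on the chosen
#' dimension, together with the difference network (per-edge mean of the
#' repair units minus per-edge mean of the no-repair units; antisymmetric
#' under swapping the strata).
#'
#' @param space an \linkS4class{ENASpace} built on all units (both strata).
#' @param unitSet the \linkS4class{ENAUnitSet} from \code{\link{splitUnits}}.
#' @param phase one of \code{gazePhases()}.
#' @param dimension kept dimension to test (default 2, the vertical axis of
#'   the published analysis).
#' @param varEqual pooled-variance Student's t (default) or Welch.
#' @return List with \code{phase}, \code{meanRepair}, \code{meanNoRepair},
#'   \code{t}, \code{df}, \code{p}, \code{d}, \code{nRepair},
#'   \code{nNoRepair} and \code{differenceNetwork}.
#' @export
repairContrast <- function(space, unitSet, phase, dimension = 2L,
                           varEqual = TRUE) {
  phase <- match.arg(phase, .PHASES)
  keep <- !unitSet@units$empty
  units <- unitSet@units[keep, , drop = FALSE]
  nU <- unitSet@nU[keep, , drop = FALSE]
  inPhase <- units$phase == phase
  rep_ <- which(inPhase & units$repair)
  nor <- which(inPhase & !units$repair)
  if (length(rep_) < 2 || length(nor) < 2)
    stop("both strata need at least 2 units in phase ", phase)
  cg <- compareGroups(space, unitSet, rep_, nor, dimension = dimension,
                      varEqual = varEqual)
  diffNet <- colMeans(nU[rep_, , drop = FALSE]) -
    colMeans(nU[nor, , drop = FALSE])
  list(phase = phase, meanRepair = cg$meanA, meanNoRepair = cg$meanB,
       t = cg$t, df = cg$df, p = cg$p, d = cg$d,
       nRepair = cg$nA, nNoRepair = cg$nB, differenceNetwork = diffNet)
}

#' Repair contrast report over phases
#'
#' Builds the shared repair-stratified space and runs
#' \code{\link{repairContrast}} for each requested phase. No
#' multiple-testing correction is applied by default (matching the
#' published analysis); \code{bonferroni = TRUE} multiplies the p-values by
#' the number of phases tested.
#'
#' @param corpus a \linkS4class{GazeCorpus} with repair flags.
#' @param phases phases to contrast (default the first three, where the
#'   published differences lie).
#' @param dimension kept dimension to test.
#' @param bonferroni apply Bonferroni correction across phases.
#' @param coded optional pre-computed \code{\link{discretize}} output.
#' @return List with \code{space}, \code{units} and \code{contrasts} (a
#'   data.frame; difference networks attached as a matrix attribute
#'   \code{"differenceNetworks"}).
#' @export
repairReport <- function(corpus, phases = .PHASES[1:3], dimension = 2L,
                         bonferroni = FALSE, coded = NULL) {
  if (is.null(coded)) coded <- discretize(corpus)
  units <- splitUnits(coded, corpus)
  space <- buildSpace(units)
  cons <- lapply(phases, function(p)
    repairContrast(space, units, p, dimension = dimension))
  df <- do.call(rbind, lapply(cons, function(cc)
    data.frame(phase = cc$phase, meanRepair = cc$meanRepair,
               meanNoRepair = cc$meanNoRepair, t = cc$t, df = cc$df,
               p = if (bonferroni) min(cc$p * length(phases), 1) else cc$p,
               d = cc$d, nRepair = cc$nRepair, nNoRepair = cc$nNoRepair,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  attr(df, "differenceNetworks") <- do.call(rbind, lapply(cons, function(cc)
    cc$differenceNetwork))
  list(space = space, units = units, contrasts = df)
}
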