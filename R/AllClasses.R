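## S4 classes for the dyadic gaze / ENA pipeline.

#' GazeCorpus: dual-stream AOI fixation data with sequence annotations
#'
#' Container for a corpus of AOI-labelled fixations from both members of
#' each dyad together with reference-action-sequence annotations. All times
#' are integer milliseconds on a clock shared by the two participants of an
#' interaction; intervals are half-open \code{[start, end)}.
#'
#' @slot fixations data.frame with columns \code{dyad_id},
#'   \code{interaction_id}, \code{role} (\code{instructor}/\code{worker}),
#'   \code{t_start_ms}, \code{t_end_ms}, \code{aoi_raw}.
#' @slot sequences data.frame with columns \code{dyad_id},
#'   \code{interaction_id}, \code{seq_index}, \code{referent_id},
#'   \code{repair} (logical), \code{reference_onset_ms} and, for each of the
#'   five phases, \code{<phase>_start_ms} / \code{<phase>_end_ms}.
#' @slot config the \linkS4class{GeneratorConfig} that produced the corpus,
#'   or \code{NULL} for observed data.
#'
#' @seealso \code{\link{readFixations}}, \code{\link{generateCorpus}},
#'   \code{\link{discretize}}
#' @export
setClass("GazeCorpus",
  representation(fixations = "data.frame", sequences = "data.frame",
                 config = "ANY"),
  prototype(config = NULL))

.FIX_COLS <- c("dyad_id", "interaction_id", "role", "t_start_ms",
               "t_end_ms", "aoi_raw")

.seqPhaseCols <- function() {
  as.vector(rbind(paste0(.PHASES, "_start_ms"), paste0(.PHASES, "_end_ms")))
}

.SEQ_COLS <- c("dyad_id", "interaction_id", "seq_index", "referent_id",
               "repair", "reference_onset_ms")

setValidity("GazeCorpus", function(object) {
  fx <- object@fixations
  sq <- object@sequences
  msgs <- character()
  if (!all(.FIX_COLS %in% names(fx)))
    return(paste("fixations must have columns:",
                 paste(.FIX_COLS, collapse = ", ")))
  if (!all(c(.SEQ_COLS, .seqPhaseCols()) %in% names(sq)))
    return(paste("sequences must have columns:",
                 paste(c(.SEQ_COLS, .seqPhaseCols()), collapse = ", ")))
  if (nrow(fx)) {
    bad <- which(!fx$role %in% .ROLES)
    if (length(bad))
      msgs <- c(msgs, paste0("unknown role label in fixation rows: ",
                             paste(utils::head(bad, 5), collapse = ", ")))
    bad <- which(fx$t_end_ms <= fx$t_start_ms)
    if (length(bad))
      msgs <- c(msgs, paste0("t_end_ms <= t_start_ms in fixation rows: ",
                             paste(utils::head(bad, 5), collapse = ", ")))
    if (!length(msgs)) {
      key <- interaction(fx$dyad_id, fx$interaction_id, fx$role, drop = TRUE)
      ord <- order(key, fx$t_start_ms)
      samepart <- !diff(as.integer(key[ord]))
      overlap <- fx$t_start_ms[ord][-1] < fx$t_end_ms[ord][-nrow(fx)] & samepart
      if (any(overlap)) {
        rows <- sort(ord[c(FALSE, overlap)])
        msgs <- c(msgs, paste0(
          "overlapping fixations within one participant; offending rows: ",
          paste(utils::head(rows, 5), collapse = ", ")))
      }
    }
  }
  if (nrow(sq)) {
    starts <- as.matrix(sq[paste0(.PHASES, "_start_ms")])
    ends <- as.matrix(sq[paste0(.PHASES, "_end_ms")])
    if (any(ends < starts))
      msgs <- c(msgs, "phase end before phase start")
    if (any(starts[, -1] != ends[, -5]))
      msgs <- c(msgs, "phases must be contiguous (each start equals the previous end)")
    key <- interaction(sq$dyad_id, sq$interaction_id, drop = TRUE)
    ord <- order(key, starts[, 1])
    same <- !diff(as.integer(key[ord]))
    if (any(starts[ord, 1][-1] < ends[ord, 5][-nrow(sq)] & same))
      msgs <- c(msgs, "overlapping sequences within one interaction")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GazeCorpus
#'
#' @param fixations,sequences data.frames as described for
#'   \linkS4class{GazeCorpus}; fixations are sorted by participant and onset.
#' @param config optional \linkS4class{GeneratorConfig} provenance.
#' @return A validated \linkS4class{GazeCorpus}.
#' @export
GazeCorpus <- function(fixations, sequences, config = NULL) {
  fixations <- as.data.frame(fixations)
  sequences <- as.data.frame(sequences)
  if (nrow(fixations)) {
    fixations$t_start_ms <- as.integer(round(fixations$t_start_ms))
    fixations$t_end_ms <- as.integer(round(fixations$t_end_ms))
    ord <- order(fixations$dyad_id, fixations$interaction_id, fixations$role,
                 fixations$t_start_ms)
    fixations <- fixations[ord, , drop = FALSE]
    rownames(fixations) <- NULL
  }
  if (nrow(sequences)) {
    sequences$repair <- as.logical(sequences$repair)
    for (cl in c("reference_onset_ms", .seqPhaseCols()))
      sequences[[cl]] <- as.integer(round(sequences[[cl]]))
    ord <- order(sequences$dyad_id, sequences$interaction_id,
                 sequences$seq_index)
    sequences <- sequences[ord, , drop = FALSE]
    rownames(sequences) <- NULL
  }
  methods::new("GazeCorpus", fixations = fixations, sequences = sequences,
               config = config)
}

#' CodedSegments: the 50 ms binary-coded dyadic gaze stream
#'
#' One row per 50 ms segment of a reference-action sequence. Codes are held
#' as integer categories per role (\code{NA} = unmapped gaze, no active
#' code), which is equivalent to the binary indicator vector with at most
#' one instructor and one worker code active; \code{\link{segmentMatrix}}
#' expands to the explicit 0/1 representation.
#'
#' @slot segments data.frame with columns \code{dyad_id},
#'   \code{interaction_id}, \code{seq_index}, \code{phase}, \code{seg_index}
#'   (0-based position on the sequence-anchored grid), \code{t_mid_ms},
#'   \code{i_cat} and \code{w_cat} (integer codes into
#'   \code{\link{gazeCategories}} for \code{"gaze8"}, or \code{w_cat} into
#'   Same/Different for \code{"same6"}).
#' @slot set \code{"gaze8"} or \code{"same6"}.
#' @slot segmentMs segment length in milliseconds.
#' @export
setClass("CodedSegments",
  representation(segments = "data.frame", set = "character",
                 segmentMs = "numeric"))

setValidity("CodedSegments", function(object) {
  need <- c("dyad_id", "interaction_id", "seq_index", "phase", "seg_index",
            "t_mid_ms", "i_cat", "w_cat")
  if (!all(need %in% names(object@segments)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (!object@set %in% c("gaze8", "same6")) return("unknown code set")
  if (object@segmentMs <= 0) return("segmentMs must be positive")
  nw <- .nWorkerCodes(object@set)
  ic <- object@segments$i_cat; wc <- object@segments$w_cat
  if (any(!is.na(ic) & (ic < 1L | ic > 4L)) ||
      any(!is.na(wc) & (wc < 1L | wc > nw)))
    return("category codes out of range")
  TRUE
})

#' ENAUnitSet: cumulative adjacency vectors per unit of analysis
#'
#' Each row is one unit of analysis (e.g. dyad-interaction by phase); the
#' count matrix \code{U} holds the number of segments in which each
#' cross-person code pair co-occurred, and \code{nU} the unit-hypersphere
#' normalisation (rows with all-zero counts are flagged empty and left zero).
#'
#' @slot units data.frame of unit keys (always \code{unit} label plus the
#'   grouping columns; \code{empty} flags all-zero units).
#' @slot U integer count matrix, units by code pairs.
#' @slot nU numeric matrix of unit-normalised rows.
#' @slot set the code set of the underlying segments.
#' @export
setClass("ENAUnitSet",
  representation(units = "data.frame", U = "matrix", nU = "matrix",
                 set = "character"))

setValidity("ENAUnitSet", function(object) {
  if (nrow(object@units) != nrow(object@U) ||
      !identical(dim(object@U), dim(object@nU)))
    return("units, U and nU must agree in dimension")
  if (any(object@U < 0)) return("counts must be non-negative")
  nz <- rowSums(object@U) > 0
  n2 <- sqrt(rowSums(object@nU^2))
  if (any(abs(n2[nz] - 1) > 1e-9))
    return("non-empty normalised rows must have unit L2 norm")
  TRUE
})

#' ENASpace: the SVD-reduced co-occurrence space
#'
#' Holds the centering vector (grand mean of the normalised adjacency
#' vectors), orthonormal loading vectors for the kept dimensions, unit
#' projections, and the least-squares node layout whose per-unit network
#' centroids approximate the projections.
#'
#' @slot set code set ("gaze8" or "same6").
#' @slot pairNames code-pair basis labels.
#' @slot center numeric centering vector over pairs.
#' @slot loadings pairs-by-d orthonormal loading matrix.
#' @slot singularValues all singular values of the centered data.
#' @slot varianceExplained proportion of variance per kept dimension.
#' @slot projections units-by-d projections of the training units.
#' @slot units data.frame of training unit keys.
#' @slot nodes codes-by-d node position matrix.
#' @slot nodeConstrained logical; FALSE for codes never observed in a
#'   co-occurrence (placed at the origin).
#' @slot positioningResidual achieved value of the node-placement objective
#'   sum over units of ||P_i - C_i||^2.
#' @export
setClass("ENASpace",
  representation(set = "character", pairNames = "character",
                 center = "numeric", loadings = "matrix",
                 singularValues = "numeric", varianceExplained = "numeric",
                 projections = "matrix", units = "data.frame",
                 nodes = "matrix", nodeConstrained = "logical",
                 positioningResidual = "numeric"))

#' AlignmentCurveSet: gaze alignment as a function of time lag
#'
#' Per phase and lag, the fraction of timeline-valid segment pairs in which
#' the worker's code at \code{t} equals the instructor's code at
#' \code{t - lag} with both participants AOI-mapped. Positive lags put the
#' instructor ahead of the worker.
#'
#' @slot curves data.frame with columns \code{phase}, \code{lag_ms},
#'   \code{alignment} (fraction in [0,1], NA when no comparable pair) and
#'   \code{n} (denominator).
#' @slot segmentMs segment length of the underlying grid.
#' @export
setClass("AlignmentCurveSet",
  representation(curves = "data.frame", segmentMs = "numeric"))

#' GeneratorConfig: the stated world of the synthetic dyad-gaze generator
#'
#' Parameters of the semi-Markov generator of dyadic AOI fixation corpora.
#' Defaults (\code{\link{defaultGeneratorConfig}}) are calibrated so the
#' synthetic corpora reproduce the published summary statistics of the
#' sandwich-making study: five-phase durations, per-phase optimal gaze lags
#' and alignment percentages, worker referent-fixation latency, and the
#' overall shared-gaze proportion.
#'
#' @slot phaseDurationMeanS named numeric (per phase), mean duration in s.
#' @slot phaseDurationCV coefficient of variation of the gamma durations.
#' @slot instructorDist 5x5 matrix (phase by Reference/Other/Target/Person/
#'   Unmapped) of instructor gaze-target probabilities.
#' @slot workerDist matching worker marginal distributions (used when a
#'   fixation is not coupled to the instructor).
#' @slot rho named numeric per phase; probability that a worker fixation
#'   copies the instructor's gaze target at lag \code{leadMs}.
#' @slot leadMs named numeric per phase; coupling lead in ms (positive =
#'   instructor leads the worker).
#' @slot dwellMeanMs,dwellCV named c(instructor, worker) lognormal fixation
#'   dwell mean (ms) and CV.
#' @slot instructorLeadMeanMs,instructorLeadCV gamma-distributed lead of the
#'   instructor's first referent fixation before reference onset (NA
#'   disables the constraint).
#' @slot workerLatencyMeanMs,workerLatencyCV gamma-distributed latency of
#'   the worker's first referent fixation after reference onset (NA
#'   disables; while active, earlier referent gaze is re-directed to another
#'   ingredient).
#' @slot repairProb probability that a sequence contains a repair.
#' @slot repairWorkerDelta 5x5 additive perturbation of \code{workerDist}
#'   in repair sequences (rows sum to 0).
#' @slot repairRhoFactor per-phase multiplicative factor on \code{rho} in
#'   repair sequences.
#' @slot nIngredients number of ingredient AOIs on the table.
#' @slot interSequenceGapMs un-coded gap between consecutive sequences.
#' @slot seed default random seed (NA = use the session RNG state).
#' @export
setClass("GeneratorConfig",
  representation(phaseDurationMeanS = "numeric", phaseDurationCV = "numeric",
                 instructorDist = "matrix", workerDist = "matrix",
                 rho = "numeric", leadMs = "numeric",
                 dwellMeanMs = "numeric", dwellCV = "numeric",
                 instructorLeadMeanMs = "numeric",
                 instructorLeadCV = "numeric",
                 workerLatencyMeanMs = "numeric", workerLatencyCV = "numeric",
                 repairProb = "numeric", repairWorkerDelta = "matrix",
                 repairRhoFactor = "numeric", nIngredients = "integer",
                 interSequenceGapMs = "numeric", seed = "integer"))

.DIST_COLS <- c(.CATEGORIES, "Unmapped")

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  for (nm in c("phaseDurationMeanS", "rho", "leadMs", "repairRhoFactor"))
    if (!identical(names(methods::slot(object, nm)), .PHASES))
      msgs <- c(msgs, paste(nm, "must be named by the five phases"))
  for (nm in c("instructorDist", "workerDist", "repairWorkerDelta")) {
    m <- methods::slot(object, nm)
    if (!identical(rownames(m), .PHASES) ||
        !identical(colnames(m), .DIST_COLS))
      msgs <- c(msgs, paste(nm, "must be a phase-by-category matrix"))
  }
  if (length(msgs)) return(paste(msgs, collapse = "; "))
  if (any(object@phaseDurationMeanS <= 0)) msgs <- c(msgs, "durations must be positive")
  if (any(object@rho < 0 | object@rho > 1)) msgs <- c(msgs, "rho must lie in [0, 1]")
  for (nm in c("instructorDist", "workerDist")) {
    m <- methods::slot(object, nm)
    if (any(m < -1e-12)) msgs <- c(msgs, paste(nm, "has negative mass"))
    if (any(abs(rowSums(m) - 1) > 1e-9))
      msgs <- c(msgs, paste(nm, "rows must sum to 1"))
  }
  if (any(abs(rowSums(object@repairWorkerDelta)) > 1e-9))
    msgs <- c(msgs, "repairWorkerDelta rows must sum to 0")
  pert <- object@workerDist + object@repairWorkerDelta
  bad <- rowSums(pert < -1e-12 | pert > 1 + 1e-12) > 0
  if (any(bad))
    msgs <- c(msgs, paste0("repair perturbation leaves the simplex in phase: ",
                           paste(.PHASES[bad], collapse = ", ")))
  if (any(object@dwellMeanMs <= 0)) msgs <- c(msgs, "dwell means must be positive")
  if (object@repairProb < 0 || object@repairProb > 1)
    msgs <- c(msgs, "repairProb must lie in [0, 1]")
  if (object@nIngredients < 2L) msgs <- c(msgs, "need at least 2 ingredients")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
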