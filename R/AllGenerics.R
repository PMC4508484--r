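## Generics, accessors and show() methods.

#' @name accessors
#' @title Accessors for dyadENA classes
#'
#' @description Slot accessors: \code{fixations}/\code{sequences} for a
#' \linkS4class{GazeCorpus}; \code{segments} for \linkS4class{CodedSegments};
#' \code{unitKeys}, \code{adjacencyCounts} (U) and
#' \code{normalizedAdjacency} (nU) for an \linkS4class{ENAUnitSet};
#' \code{projections}, \code{loadings}, \code{centerVector},
#' \code{nodePositions} and \code{varianceExplained} for an
#' \linkS4class{ENASpace}; \code{curves} for an
#' \linkS4class{AlignmentCurveSet}.
#'
#' @param x object to access.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("fixations", function(x) standardGeneric("fixations"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("unitKeys", function(x) standardGeneric("unitKeys"))
#' @rdname accessors
#' @export
setGeneric("adjacencyCounts", function(x) standardGeneric("adjacencyCounts"))
#' @rdname accessors
#' @export
setGeneric("normalizedAdjacency",
           function(x) standardGeneric("normalizedAdjacency"))
#' @rdname accessors
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))
#' @rdname accessors
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setGeneric("centerVector", function(x) standardGeneric("centerVector"))
#' @rdname accessors
#' @export
setGeneric("nodePositions", function(x) standardGeneric("nodePositions"))
#' @rdname accessors
#' @export
setGeneric("varianceExplained",
           function(x) standardGeneric("varianceExplained"))
#' @rdname accessors
#' @export
setGeneric("curves", function(x) standardGeneric("curves"))

#' @rdname accessors
#' @export
setMethod("fixations", "GazeCorpus", function(x) x@fixations)
#' @rdname accessors
#' @export
setMethod("sequences", "GazeCorpus", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("segments", "CodedSegments", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("unitKeys", "ENAUnitSet", function(x) x@units)
#' @rdname accessors
#' @export
setMethod("unitKeys", "ENASpace", function(x) x@units)
#' @rdname accessors
#' @export
setMethod("adjacencyCounts", "ENAUnitSet", function(x) x@U)
#' @rdname accessors
#' @export
setMethod("normalizedAdjacency", "ENAUnitSet", function(x) x@nU)
#' @rdname accessors
#' @export
setMethod("projections", "ENASpace", function(x) x@projections)
#' @rdname accessors
#' @export
setMethod("loadings", "ENASpace", function(x) x@loadings)
#' @rdname accessors
#' @export
setMethod("centerVector", "ENASpace", function(x) x@center)
#' @rdname accessors
#' @export
setMethod("nodePositions", "ENASpace", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("varianceExplained", "ENASpace", function(x) x@varianceExplained)
#' @rdname accessors
#' @export
setMethod("curves", "AlignmentCurveSet", function(x) x@curves)

setMethod("show", "GazeCorpus", function(object) {
  fx <- object@fixations; sq <- object@sequences
  cat("GazeCorpus:", nrow(fx), "fixations,", nrow(sq), "sequences,",
      length(unique(fx$dyad_id)), "dyads\n")
  if (nrow(sq))
    cat("  repair sequences:", sum(sq$repair), "of", nrow(sq), "\n")
  if (!is.null(object@config)) cat("  synthetic (generator config attached)\n")
})

setMethod("show", "CodedSegments", function(object) {
  s <- object@segments
  cat("CodedSegments (", object@set, "): ", nrow(s), " segments of ",
      object@segmentMs, " ms\n", sep = "")
  if (nrow(s)) {
    cov <- c(instructor = mean(!is.na(s$i_cat)), worker = mean(!is.na(s$w_cat)))
    cat("  coded fraction: instructor ", round(cov[1], 3), ", worker ",
        round(cov[2], 3), "\n", sep = "")
  }
})

setMethod("show", "ENAUnitSet", function(object) {
  cat("ENAUnitSet (", object@set, "): ", nrow(object@U), " units x ",
      ncol(object@U), " code pairs; ", sum(object@units$empty),
      " empty\n", sep = "")
})

setMethod("show", "ENASpace", function(object) {
  d <- ncol(object@loadings)
  cat("ENASpace (", object@set, "): ", nrow(object@projections),
      " units, ", d, " kept dimensions\n", sep = "")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * object@varianceExplained), collapse = ", "),
      "\n")
  cat("  node-positioning residual:",
      format(object@positioningResidual, digits = 4), "\n")
})

setMethod("show", "AlignmentCurveSet", function(object) {
  cv <- object@curves
  cat("AlignmentCurveSet:", length(unique(cv$phase)), "phases,",
      length(unique(cv$lag_ms)), "lags\n")
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig\n  phase duration means (s): ",
      paste(sprintf("%s=%.2f", .PHASES, object@phaseDurationMeanS),
            collapse = ", "), "\n", sep = "")
  cat("  coupling rho: ",
      paste(sprintf("%.2f", object@rho), collapse = ", "),
      ";  leads (ms): ", paste(object@leadMs, collapse = ", "), "\n", sep = "")
  cat("  repair probability: ", object@repairProb, "\n", sep = "")
})
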