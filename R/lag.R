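## Lag-scan gaze alignment, same/different recoding, shifted ENA space.

#' Recode worker gaze as Same/Different relative to the instructor
#'
#' Produces the 6-code representation of the alignment analysis: the four
#' instructor codes pass through; the worker code becomes \code{W.Same}
#' when both participants' codes refer to the same target category,
#' \code{W.Different} when both are coded and differ, and inactive when
#' either participant is uncoded (unmapped gaze never counts as either).
#'
#' @param x a \linkS4class{CodedSegments} on the \code{"gaze8"} set.
#' @return A \linkS4class{CodedSegments} on the \code{"same6"} set.
#' @export
#' @examples
#' corpus <- generateCorpus(defaultGeneratorConfig(), nDyads = 1,
#'                          nSequences = 2, seed = 1)
#' recodeSameDifferent(discretize(corpus))
recodeSameDifferent <- function(x) {
  stopifnot(methods::is(x, "CodedSegments"))
  if (x@set != "gaze8") stop("recoding requires the 8-code segment stream")
  s <- segments(x)
  both <- !is.na(s$i_cat) & !is.na(s$w_cat)
  w <- rep(NA_integer_, nrow(s))
  w[both & s$i_cat == s$w_cat] <- 1L   # Same
  w[both & s$i_cat != s$w_cat] <- 2L   # Different
  s$w_cat <- w
  methods::new("CodedSegments", segments = s, set = "same6",
               segmentMs = x@segmentMs)
}

## Ordered per-sequence code arrays padded with sentinel gaps so that a
## global index shift of up to padSegments never crosses a sequence
## boundary. Returns integer category vectors with NA padding and a
## sequence id vector (0 = padding).
.paddedStreams <- function(s, padSegments) {
  ord <- order(s$dyad_id, s$interaction_id, s$seq_index, s$seg_index)
  s <- s[ord, , drop = FALSE]
  seqkey <- paste(s$dyad_id, s$interaction_id, s$seq_index, sep = "\r")
  runs <- rle(seqkey)
  nseq <- length(runs$lengths)
  pad <- padSegments
  total <- nrow(s) + pad * (nseq + 1L)
  icat <- wcat <- rep(NA_integer_, total)
  sid <- integer(total)
  ph <- rep(NA_character_, total)
  pos <- pad
  starts <- integer(nseq)
  for (k in seq_len(nseq)) {
    len <- runs$lengths[k]
    idx <- pos + seq_len(len)
    starts[k] <- pos + 1L
    sid[idx] <- k
    pos <- pos + len + pad
  }
  fill <- sid > 0L
  icat[fill] <- s$i_cat
  wcat[fill] <- s$w_cat
  ph[fill] <- s$phase
  list(i = icat, w = wcat, sid = sid, phase = ph)
}

#' Gaze alignment curves over time lags
#'
#' For each phase and each lag tau on the segment grid, the fraction of
#' phase segments t (pooled over all dyads and sequences) in which the
#' worker's code at t equals the instructor's code at t - tau, both being
#' AOI-mapped. Positive lags put the instructor ahead of the worker. The
#' denominator counts every segment whose shifted partner lies inside the
#' same sequence's recorded timeline (comparisons never straddle sequence
#' boundaries); segments with unmapped gaze stay in the denominator but
#' cannot contribute a match. Lags with an empty denominator are NA.
#'
#' @param x a \linkS4class{CodedSegments} on the \code{"gaze8"} set.
#' @param lagMinMs,lagMaxMs,stepMs lag grid in ms (defaults -2000..2000 by
#'   50); the step must be a multiple of the segment length.
#' @param phases phases to scan (default all five).
#' @return An \linkS4class{AlignmentCurveSet}.
#' @export
alignmentCurves <- function(x, lagMinMs = -2000, lagMaxMs = 2000,
                            stepMs = x@segmentMs, phases = .PHASES) {
  stopifnot(methods::is(x, "CodedSegments"))
  if (stepMs %% x@segmentMs != 0)
    stop("lag step must be a multiple of the segment length")
  lags <- seq(lagMinMs, lagMaxMs, by = stepMs)
  if (any(lags %% x@segmentMs != 0))
    stop("lags must lie on the segment grid")
  s <- segments(x)
  maxShift <- max(abs(lags)) %/% x@segmentMs
  st <- .paddedStreams(s, as.integer(maxShift) + 1L)
  phaseIdx <- lapply(phases, function(p) which(!is.na(st$phase) &
                                               st$phase == p))
  out <- vector("list", length(phases) * length(lags))
  k <- 0L
  n <- length(st$i)
  for (li in seq_along(lags)) {
    sh <- lags[li] %/% x@segmentMs
    ## instructor stream shifted: partner of t is t - sh
    src <- seq_len(n) - sh
    ok <- src >= 1L & src <= n
    valid <- logical(n)
    valid[ok] <- st$sid[src[ok]] == st$sid[ok] & st$sid[ok] > 0L
    match_ <- logical(n)
    match_[valid] <- !is.na(st$w[valid]) & !is.na(st$i[src[valid]]) &
      st$w[valid] == st$i[src[valid]]
    for (pi in seq_along(phases)) {
      idx <- phaseIdx[[pi]]
      den <- sum(valid[idx])
      k <- k + 1L
      out[[k]] <- data.frame(phase = phases[pi], lag_ms = lags[li],
                             alignment = if (den) sum(match_[idx]) / den
                                         else NA_real_,
                             n = den, stringsAsFactors = FALSE)
    }
  }
  cv <- do.call(rbind, out)
  cv <- cv[order(match(cv$phase, .PHASES), cv$lag_ms), , drop = FALSE]
  rownames(cv) <- NULL
  methods::new("AlignmentCurveSet", curves = cv, segmentMs = x@segmentMs)
}

#' Optimal lag of an alignment curve
#'
#' The lag maximising alignment, per phase. Ties (within 1e-9) are broken
#' toward the smallest absolute lag, then toward the positive lag; a
#' completely flat curve returns 0 with a warning. Lags with undefined
#' alignment are excluded from the search.
#'
#' @param x an \linkS4class{AlignmentCurveSet}.
#' @param phase optional single phase; default all phases in \code{x}.
#' @param minDenomFrac,minDenom lags whose denominator is below
#'   \code{max(minDenom, minDenomFrac * max(n))} are treated as undefined
#'   for the peak search: at extreme lags only a handful of unusually long
#'   phase occurrences remain comparable and their alignment fraction is
#'   pure noise.
#' @return data.frame with columns \code{phase}, \code{lag_ms},
#'   \code{alignment}, \code{tied}.
#' @export
optimalLag <- function(x, phase = NULL, minDenomFrac = 0.05, minDenom = 20L) {
  cv <- curves(x)
  phases <- if (is.null(phase)) unique(cv$phase) else phase
  out <- lapply(phases, function(p) {
    sub <- cv[cv$phase == p & !is.na(cv$alignment), , drop = FALSE]
    if (nrow(sub)) {
      cut <- max(minDenom, minDenomFrac * max(sub$n))
      ok <- sub$n >= cut
      if (any(ok)) sub <- sub[ok, , drop = FALSE]
    }
    if (!nrow(sub)) stop("no defined lag for phase ", p)
    top <- max(sub$alignment)
    cand <- sub[sub$alignment >= top - 1e-9, , drop = FALSE]
    tied <- nrow(cand) > 1L
    if (tied && nrow(cand) == sum(!is.na(cv$alignment[cv$phase == p]))) {
      warning("flat alignment curve for phase ", p, "; returning lag 0")
      pick <- cand[which.min(abs(cand$lag_ms - 0)), , drop = FALSE]
      pick$lag_ms <- 0
    } else {
      ord <- order(abs(cand$lag_ms), -sign(cand$lag_ms))
      pick <- cand[ord[1L], , drop = FALSE]
      if (tied) warning("tied peak alignment for phase ", p,
                        "; smallest-|lag| (then positive) rule applied")
    }
    data.frame(phase = p, lag_ms = pick$lag_ms, alignment = pick$alignment,
               tied = tied, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Shift the worker stream by per-phase lags
#'
#' Replaces the worker code of each segment in phase p by the worker code
#' observed \code{lag_p} later on the same sequence's segment grid (so that
#' at the optimal lag the shifted worker aligns with the instructor at zero
#' lag). Segments whose shifted partner falls outside the sequence become
#' uncoded for the worker.
#'
#' @param x a \linkS4class{CodedSegments} on the \code{"gaze8"} set.
#' @param lagsMs named numeric of per-phase lags (ms, as from
#'   \code{\link{optimalLag}}); must be multiples of the segment length.
#' @return A \linkS4class{CodedSegments} on the \code{"gaze8"} set.
#' @export
shiftWorker <- function(x, lagsMs) {
  stopifnot(methods::is(x, "CodedSegments"))
  if (any(lagsMs %% x@segmentMs != 0))
    stop("lags must lie on the segment grid")
  s <- segments(x)
  ord <- order(s$dyad_id, s$interaction_id, s$seq_index, s$seg_index)
  s <- s[ord, , drop = FALSE]
  seqkey <- paste(s$dyad_id, s$interaction_id, s$seq_index, sep = "\r")
  newW <- rep(NA_integer_, nrow(s))
  sh <- lagsMs[s$phase] %/% x@segmentMs
  tgt <- seq_len(nrow(s)) + sh
  ok <- tgt >= 1L & tgt <= nrow(s)
  ok[ok] <- seqkey[tgt[ok]] == seqkey[ok]
  newW[ok] <- s$w_cat[tgt[ok]]
  s$w_cat <- newW
  rownames(s) <- NULL
  methods::new("CodedSegments", segments = s, set = "gaze8",
               segmentMs = x@segmentMs)
}

#' Lag-shifted ENA space on the Same/Different code set
#'
#' Shifts the worker stream of each phase by that phase's optimal lag,
#' recodes worker gaze as Same/Different, accumulates dyad-interaction by
#' phase units and builds the reduced space -- the alignment-analysis
#' counterpart of the phase-network space.
#'
#' @param x a \linkS4class{CodedSegments} on the \code{"gaze8"} set.
#' @param lagsMs named per-phase lags in ms; if missing they are recovered
#'   with \code{\link{alignmentCurves}} + \code{\link{optimalLag}}.
#' @param d kept dimensions.
#' @return List with \code{space} (\linkS4class{ENASpace}),
#'   \code{units} (\linkS4class{ENAUnitSet}) and \code{lagsMs}.
#' @export
shiftedENA <- function(x, lagsMs = NULL, d = 2L) {
  if (is.null(lagsMs)) {
    ol <- optimalLag(alignmentCurves(x))
    lagsMs <- stats::setNames(ol$lag_ms, ol$phase)
  }
  miss <- setdiff(unique(segments(x)$phase), names(lagsMs))
  if (length(miss)) stop("missing lags for phases: ",
                         paste(miss, collapse = ", "))
  shifted <- shiftWorker(x, lagsMs)
  recoded <- recodeSameDifferent(shifted)
  units <- accumulateUnits(recoded)
  list(space = buildSpace(units, d = d), units = units, lagsMs = lagsMs)
}
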