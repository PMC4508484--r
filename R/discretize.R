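## 50 ms discretisation of dual fixation streams over sequence phases.

#' Discretise a corpus into coded 50 ms segments
#'
#' Tiles the timeline of every reference-action sequence with contiguous
#' segments of \code{segmentMs}, anchored at the sequence start. Each
#' segment takes, per participant, the code of the fixation covering its
#' midpoint (half-open fixation intervals, so a fixation ending exactly at
#' the midpoint does not cover it), re-coded relative to the sequence's
#' referent via \code{\link{mapGazeCode}}. The segment's phase is the phase
#' window containing its midpoint; midpoints falling in no phase (possible
#' only with degenerate annotations) are dropped. Unmapped gaze leaves the
#' participant uncoded in that segment.
#'
#' @param corpus a \linkS4class{GazeCorpus}.
#' @param segmentMs segment length in ms (default 50).
#' @return A \linkS4class{CodedSegments} on the \code{"gaze8"} code set.
#' @export
#' @examples
#' corpus <- generateCorpus(defaultGeneratorConfig(), nDyads = 1,
#'                          nSequences = 2, seed = 1)
#' discretize(corpus)
discretize <- function(corpus, segmentMs = 50) {
  stopifnot(methods::is(corpus, "GazeCorpus"), segmentMs > 0)
  sq <- sequences(corpus)
  fx <- fixations(corpus)
  if (!nrow(sq))
    return(methods::new("CodedSegments", segments = .emptySegmentTable(),
                        set = "gaze8", segmentMs = segmentMs))
  starts <- as.matrix(sq[paste0(.PHASES, "_start_ms")])
  ends <- as.matrix(sq[paste0(.PHASES, "_end_ms")])
  if (any(starts == ends))
    warning("zero-length phases contribute no segments")
  fkey <- paste(fx$dyad_id, fx$interaction_id, fx$role, sep = "\r")
  fsplit <- split(seq_len(nrow(fx)), fkey)

  out <- vector("list", nrow(sq))
  for (i in seq_len(nrow(sq))) {
    s0 <- starts[i, 1]; s5 <- ends[i, 5]
    nseg <- floor((s5 - s0) / segmentMs)
    if (nseg < 1) next
    mids <- s0 + segmentMs * (seq_len(nseg) - 1) + segmentMs / 2
    ## phase of each midpoint (phases are contiguous within [s0, s5))
    ph <- rep(NA_integer_, nseg)
    for (p in 1:5) ph[mids >= starts[i, p] & mids < ends[i, p]] <- p
    keep <- !is.na(ph)
    icat <- .codeAtTimes(fx, fsplit,
                         paste(sq$dyad_id[i], sq$interaction_id[i],
                               "instructor", sep = "\r"),
                         mids, sq$referent_id[i])
    wcat <- .codeAtTimes(fx, fsplit,
                         paste(sq$dyad_id[i], sq$interaction_id[i],
                               "worker", sep = "\r"),
                         mids, sq$referent_id[i])
    out[[i]] <- data.frame(
      dyad_id = sq$dyad_id[i], interaction_id = sq$interaction_id[i],
      seq_index = sq$seq_index[i], phase = .PHASES[ph[keep]],
      seg_index = which(keep) - 1L, t_mid_ms = mids[keep],
      i_cat = icat[keep], w_cat = wcat[keep], stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(segs)) segs <- .emptySegmentTable()
  rownames(segs) <- NULL
  methods::new("CodedSegments", segments = segs, set = "gaze8",
               segmentMs = segmentMs)
}

## Integer category of the fixation covering each time point, for one
## participant stream (NA when no fixation covers it or gaze is unmapped).
.codeAtTimes <- function(fx, fsplit, key, times, referent) {
  idx <- fsplit[[key]]
  if (is.null(idx)) return(rep(NA_integer_, length(times)))
  st <- fx$t_start_ms[idx]; en <- fx$t_end_ms[idx]   # sorted by onset
  j <- findInterval(times, st)
  hit <- j >= 1L & times < en[pmax(j, 1L)]
  cat <- rep(NA_integer_, length(times))
  cat[hit] <- .mapCategory(fx$aoi_raw[idx][j[hit]], referent)
  cat
}

.emptySegmentTable <- function() {
  data.frame(dyad_id = character(), interaction_id = integer(),
             seq_index = integer(), phase = character(),
             seg_index = integer(), t_mid_ms = numeric(),
             i_cat = integer(), w_cat = integer(), stringsAsFactors = FALSE)
}

#' Expand coded segments to a binary indicator matrix
#'
#' @param x a \linkS4class{CodedSegments}.
#' @return Integer 0/1 matrix, one row per segment and one column per code
#'   of \code{codeSet(x@set)}; at most one instructor and one worker code
#'   are active per row.
#' @export
segmentMatrix <- function(x) {
  stopifnot(methods::is(x, "CodedSegments"))
  s <- segments(x)
  codes <- codeSet(x@set)
  nw <- .nWorkerCodes(x@set)
  m <- matrix(0L, nrow(s), length(codes), dimnames = list(NULL, codes))
  ic <- s$i_cat
  ok <- !is.na(ic)
  m[cbind(which(ok), ic[ok])] <- 1L
  wc <- s$w_cat
  ok <- !is.na(wc)
  m[cbind(which(ok), 4L + wc[ok])] <- 1L
  m
}
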