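## Leave-one-dyad-out nearest-centroid phase prediction.

#' Leave-one-dyad-out ENA space with phase centroids
#'
#' Builds the dyad-interaction by phase ENA space from all units except the
#' held-out dyad's, and computes the per-phase centroids of the training
#' unit projections.
#'
#' @param x a \linkS4class{CodedSegments} on the \code{"gaze8"} set.
#' @param holdout the dyad id to exclude.
#' @param d kept dimensions.
#' @return List with \code{space}, \code{centroids} (phase-by-d matrix) and
#'   \code{holdout}.
#' @export
looSpace <- function(x, holdout, d = 2L) {
  s <- segments(x)
  if (!holdout %in% s$dyad_id)
    stop("held-out dyad not present: ", holdout)
  train <- methods::new("CodedSegments",
                        segments = s[s$dyad_id != holdout, , drop = FALSE],
                        set = x@set, segmentMs = x@segmentMs)
  units <- accumulateUnits(train)
  space <- buildSpace(units, d = d)
  P <- space@projections
  ph <- space@units$phase
  centroids <- do.call(rbind, lapply(.PHASES, function(p)
    colMeans(P[ph == p, , drop = FALSE])))
  rownames(centroids) <- .PHASES
  list(space = space, centroids = centroids, holdout = holdout)
}

#' Sample random gaze windows from a corpus
#'
#' Samples fixed-length windows of the coded stream uniformly over the
#' admissible (sequence, phase, start) positions: a window must lie fully
#' inside a single phase occurrence, so phases shorter than the window in a
#' given sequence contribute no positions there. Sampling is with
#' replacement; phases with no admissible position anywhere are reported
#' undersampled via the \code{n} attribute.
#'
#' @param x a \linkS4class{CodedSegments}.
#' @param windowMs window length (must be a multiple of the segment
#'   length); the study used 200 and 1000 ms.
#' @param nPerPhase windows sampled per actual phase (default 50).
#' @param dyads optional dyad ids to restrict sampling to (e.g. the
#'   held-out dyad).
#' @return data.frame with one row per window: unit keys, \code{phase},
#'   \code{start_seg} and \code{n_seg}.
#' @export
sampleWindows <- function(x, windowMs, nPerPhase = 50L, dyads = NULL) {
  stopifnot(methods::is(x, "CodedSegments"))
  if (windowMs %% x@segmentMs != 0)
    stop("window must be a multiple of the segment length")
  wseg <- as.integer(windowMs %/% x@segmentMs)
  s <- segments(x)
  if (!is.null(dyads)) s <- s[s$dyad_id %in% dyads, , drop = FALSE]
  ## contiguous phase runs within sequences
  key <- paste(s$dyad_id, s$interaction_id, s$seq_index, s$phase, sep = "\r")
  ord <- order(s$dyad_id, s$interaction_id, s$seq_index, s$seg_index)
  s <- s[ord, , drop = FALSE]
  key <- key[ord]
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  runPhase <- s$phase[starts]
  nAdm <- pmax(runs$lengths - wseg + 1L, 0L)
  out <- list()
  for (p in .PHASES) {
    ri <- which(runPhase == p & nAdm > 0L)
    if (!length(ri)) next
    wts <- nAdm[ri]
    pick <- ri[sample.int(length(ri), nPerPhase, replace = TRUE, prob = wts)]
    offs <- vapply(pick, function(r) sample.int(nAdm[r], 1L) - 1L,
                   integer(1))
    first <- starts[pick] + offs
    out[[p]] <- data.frame(
      dyad_id = s$dyad_id[first], interaction_id = s$interaction_id[first],
      seq_index = s$seq_index[first], phase = p,
      start_row = first, start_seg = s$seg_index[first], n_seg = wseg,
      stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, out)
  rownames(win) <- NULL
  attr(win, "n") <- stats::setNames(
    vapply(.PHASES, function(p) sum(win$phase == p), integer(1)), .PHASES)
  attr(win, "sorted_segments") <- s
  win
}

#' Classify gaze windows by nearest phase centroid
#'
#' Accumulates each window's segments into an adjacency vector, normalises,
#' centers with the training mean, projects on the kept dimensions and
#' assigns the phase with the nearest centroid (Euclidean distance in the
#' kept space). Windows with no co-occurrence at all are uncodable and
#' returned as \code{NA}; exact ties are broken by phase order and flagged.
#'
#' @param windows output of \code{\link{sampleWindows}}.
#' @param loo output of \code{\link{looSpace}} (space + centroids).
#' @return data.frame \code{windows} plus columns \code{predicted} and
#'   \code{tied}.
#' @export
classifyWindows <- function(windows, loo) {
  s <- attr(windows, "sorted_segments")
  space <- loo$space
  centroids <- loo$centroids
  nw <- .nWorkerCodes(space@set)
  pred <- rep(NA_character_, nrow(windows))
  tied <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    rows <- windows$start_row[i] + seq_len(windows$n_seg[i]) - 1L
    ic <- s$i_cat[rows]; wc <- s$w_cat[rows]
    ok <- !is.na(ic) & !is.na(wc)
    if (!any(ok)) next                        # uncodable
    U <- tabulate(.pairIndex(ic[ok], wc[ok], space@set), 4L * nw)
    pr <- projectUnits(space, normalizeAdjacency(U))
    dd <- sqrt(rowSums(sweep(centroids, 2, pr)^2))
    best <- which(dd <= min(dd) + 1e-12)
    pred[i] <- rownames(centroids)[best[1L]]
    tied[i] <- length(best) > 1L
  }
  windows$predicted <- pred
  windows$tied <- tied
  windows
}

#' Confusion matrix of phase predictions
#'
#' @param classified output of \code{\link{classifyWindows}} (possibly
#'   concatenated over held-out dyads / window lengths).
#' @return List with \code{matrix} (5x5 counts, rows actual, columns
#'   predicted), \code{recall} per phase, \code{accuracy}, and
#'   \code{nUncodable}.
#' @export
phaseConfusion <- function(classified) {
  ok <- !is.na(classified$predicted)
  m <- table(factor(classified$phase[ok], levels = .PHASES),
             factor(classified$predicted[ok], levels = .PHASES))
  m <- unclass(m)
  names(dimnames(m)) <- c("actual", "predicted")
  rec <- diag(m) / pmax(rowSums(m), 1L)
  list(matrix = m, recall = rec,
       accuracy = sum(diag(m)) / max(sum(m), 1L),
       nUncodable = sum(!ok))
}

#' Leave-one-dyad-out phase prediction
#'
#' Full validation loop: for each held-out dyad, build the training space
#' from the other dyads, sample random windows from the held-out dyad's
#' stream, classify them by nearest phase centroid and pool the confusion
#' matrices.
#'
#' @param x a \linkS4class{CodedSegments} on the \code{"gaze8"} set.
#' @param windowMs window length(s) in ms (default \code{c(200, 1000)}).
#' @param nPerPhase windows per phase per held-out dyad.
#' @param holdouts dyads to hold out (default: every dyad in turn).
#' @param d kept dimensions.
#' @return Named list (one entry per window length) of
#'   \code{\link{phaseConfusion}} results.
#' @export
predictPhases <- function(x, windowMs = c(200, 1000), nPerPhase = 50L,
                          holdouts = NULL, d = 2L) {
  s <- segments(x)
  if (is.null(holdouts)) holdouts <- unique(s$dyad_id)
  out <- list()
  for (wm in windowMs) {
    cls <- list()
    for (h in holdouts) {
      loo <- looSpace(x, h, d = d)
      win <- sampleWindows(x, wm, nPerPhase, dyads = h)
      if (is.null(win) || !nrow(win)) next
      cls[[h]] <- classifyWindows(win, loo)
    }
    pooled <- do.call(rbind, lapply(cls, function(cl)
      cl[c("phase", "predicted")]))
    out[[as.character(wm)]] <- phaseConfusion(pooled)
  }
  out
}
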