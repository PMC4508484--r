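## Group summaries: mean networks, centroids, centroid t-tests.

#' Mean network and centroid of a group of units
#'
#' The mean network is the arithmetic per-edge mean of the group members'
#' normalised adjacency vectors (exact linearity: partition means recombine
#' weighted by part sizes). The group centroid is the mean of the member
#' projections; per-dimension 95\% confidence half-widths are
#' t-based (\code{qt(0.975, n - 1) * sd / sqrt(n)}), \code{NA} for n = 1.
#'
#' @param space an \linkS4class{ENASpace}.
#' @param unitSet the \linkS4class{ENAUnitSet} the space was built from (or
#'   a compatible one).
#' @param which logical or integer index into the non-empty units selecting
#'   the group, or a named grouping: \code{by = "phase"} summarises every
#'   level.
#' @param by optional grouping column of the unit keys; when given,
#'   \code{which} is ignored and a list of summaries (one per level) is
#'   returned.
#' @return A list with \code{meanNetwork} (named per-edge means),
#'   \code{centroid}, \code{ciHalfWidth}, \code{n} -- or a named list of
#'   such summaries when \code{by} is used.
#' @export
meanNetwork <- function(space, unitSet, which = NULL, by = NULL) {
  keep <- !unitSet@units$empty
  nU <- unitSet@nU[keep, , drop = FALSE]
  units <- unitSet@units[keep, , drop = FALSE]
  P <- projectUnits(space, nU)
  one <- function(idx) {
    n <- length(idx)
    if (!n) stop("empty group")
    ci <- if (n > 1)
      stats::qt(0.975, n - 1) * apply(P[idx, , drop = FALSE], 2, stats::sd) /
        sqrt(n)
    else rep(NA_real_, ncol(P))
    list(meanNetwork = colMeans(nU[idx, , drop = FALSE]),
         centroid = colMeans(P[idx, , drop = FALSE]),
         ciHalfWidth = ci, n = n)
  }
  if (!is.null(by)) {
    lv <- unique(units[[by]])
    return(stats::setNames(lapply(lv, function(l) one(which(units[[by]] == l))),
                           lv))
  }
  if (is.null(which)) which <- seq_len(nrow(nU))
  if (is.logical(which)) which <- which(which)
  one(which)
}

#' Compare two groups of networks on one dimension
#'
#' Two-sample t-test on the unit projections of the two groups along one
#' kept dimension (Student's pooled-variance test by default, matching the
#' published analysis; Welch via \code{varEqual = FALSE}), with Cohen's d
#' computed from the pooled standard deviation.
#'
#' @param space an \linkS4class{ENASpace}.
#' @param unitSet the \linkS4class{ENAUnitSet} holding both groups.
#' @param groupA,groupB logical or integer indices into the non-empty units.
#' @param dimension which kept dimension to test (default 1).
#' @param varEqual pooled-variance Student's t (default) or Welch.
#' @return List with \code{t}, \code{df}, \code{p}, \code{d} (Cohen),
#'   \code{meanA}, \code{meanB}, \code{nA}, \code{nB}.
#' @export
compareGroups <- function(space, unitSet, groupA, groupB, dimension = 1L,
                          varEqual = TRUE) {
  keep <- !unitSet@units$empty
  nU <- unitSet@nU[keep, , drop = FALSE]
  P <- projectUnits(space, nU)
  if (is.logical(groupA)) groupA <- which(groupA)
  if (is.logical(groupB)) groupB <- which(groupB)
  a <- P[groupA, dimension]; b <- P[groupB, dimension]
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 units")
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
              (length(b) - 1) * stats::var(b)) /
             (length(a) + length(b) - 2))
  if (sp < .Machine$double.eps) {
    ## degenerate: no variance in either group
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0, d = if (eq) 0 else Inf,
                meanA = mean(a), meanB = mean(b),
                nA = length(a), nB = length(b)))
  }
  tt <- stats::t.test(a, b, var.equal = varEqual)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(a) - mean(b)) / sp,
       meanA = mean(a), meanB = mean(b), nA = length(a), nB = length(b))
}
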