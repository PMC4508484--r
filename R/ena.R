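## ENA core: adjacency accumulation, normalisation, SVD space, node layout.

#' Accumulate cumulative adjacency vectors per unit of analysis
#'
#' Counts, for every unit (default dyad-interaction by phase), the number of
#' 50 ms segments in which each cross-person code pair co-occurred. A
#' segment increments at most one pair (one instructor and one worker code
#' can be active); segments with either participant uncoded contribute
#' nothing. Units whose counts are all zero are flagged \code{empty}.
#'
#' @param x a \linkS4class{CodedSegments}.
#' @param by character vector of grouping columns from \code{segments(x)}
#'   (plus \code{"repair"} which is looked up from \code{sequences}); the
#'   default is the dyad-interaction-by-phase unit of the phase analysis.
#' @param corpus required when \code{"repair"} is in \code{by}: the
#'   \linkS4class{GazeCorpus} carrying the sequence repair flags.
#' @param dropEmpty drop all-zero units instead of flagging them.
#' @return An \linkS4class{ENAUnitSet}.
#' @export
#' @examples
#' corpus <- generateCorpus(defaultGeneratorConfig(), nDyads = 2,
#'                          nSequences = 4, seed = 1)
#' accumulateUnits(discretize(corpus))
accumulateUnits <- function(x, by = c("dyad_id", "interaction_id", "phase"),
                            corpus = NULL, dropEmpty = FALSE) {
  stopifnot(methods::is(x, "CodedSegments"))
  s <- segments(x)
  if ("repair" %in% by) {
    if (is.null(corpus))
      stop("grouping by repair requires the corpus with sequence annotations")
    sq <- sequences(corpus)
    key <- paste(s$dyad_id, s$interaction_id, s$seq_index, sep = "\r")
    skey <- paste(sq$dyad_id, sq$interaction_id, sq$seq_index, sep = "\r")
    s$repair <- sq$repair[match(key, skey)]
  }
  miss <- setdiff(by, names(s))
  if (length(miss)) stop("unknown grouping columns: ",
                         paste(miss, collapse = ", "))
  pairs <- codePairs(x@set)
  np <- length(pairs)
  keyDf <- s[by]
  key <- do.call(paste, c(keyDf, sep = "\r"))
  ukey <- !duplicated(key)
  units <- keyDf[ukey, , drop = FALSE]
  uid <- match(key, key[ukey])
  ok <- !is.na(s$i_cat) & !is.na(s$w_cat)
  pidx <- .pairIndex(s$i_cat[ok], s$w_cat[ok], x@set)
  U <- matrix(0L, nrow(units), np, dimnames = list(NULL, pairs))
  if (any(ok)) {
    tab <- table(factor(uid[ok], levels = seq_len(nrow(units))),
                 factor(pidx, levels = seq_len(np)))
    U[] <- as.integer(tab)
  }
  units$empty <- rowSums(U) == 0L
  units$unit <- do.call(paste, c(units[by], sep = "."))
  rownames(units) <- NULL
  if (dropEmpty) {
    keep <- !units$empty
    units <- units[keep, , drop = FALSE]
    U <- U[keep, , drop = FALSE]
    rownames(units) <- NULL
  }
  nU <- .normalizeRows(U)
  methods::new("ENAUnitSet", units = units, U = U, nU = nU, set = x@set)
}

#' Normalise a cumulative adjacency vector to the unit hypersphere
#'
#' Divides each value by the square root of the sum of squares of the
#' vector, controlling for differences in total co-occurrence frequency.
#'
#' @param U numeric vector (or matrix of row vectors) of co-occurrence
#'   counts.
#' @return Vector or matrix of the same shape with unit L2 norm per
#'   (non-zero) row.
#' @export
#' @examples
#' normalizeAdjacency(c(2, 1, 0))
normalizeAdjacency <- function(U) {
  if (is.matrix(U)) return(.normalizeRows(U, strict = TRUE))
  n <- sqrt(sum(U^2))
  if (n == 0) stop("empty unit: cannot normalise a zero adjacency vector")
  U / n
}

.normalizeRows <- function(U, strict = FALSE) {
  n <- sqrt(rowSums(U^2))
  if (strict && any(n == 0))
    stop("empty unit: cannot normalise a zero adjacency vector")
  n[n == 0] <- 1
  U / n
}

#' Build the reduced ENA space by singular value decomposition
#'
#' Centers the normalised adjacency vectors on their grand mean, decomposes
#' by SVD and keeps the top \code{d} dimensions. The sign of each loading
#' vector is fixed so that its largest-magnitude entry is positive, making
#' the output deterministic. Unit projections are the centered vectors on
#' the kept loadings; their mean is zero by construction. Node positions
#' are computed by \code{\link{positionNodes}} unless \code{position =
#' FALSE}.
#'
#' @param unitSet an \linkS4class{ENAUnitSet} (empty units are excluded).
#' @param d number of kept dimensions (default 2).
#' @param position also solve the node-placement least squares (default).
#' @return An \linkS4class{ENASpace}.
#' @export
buildSpace <- function(unitSet, d = 2L, position = TRUE) {
  stopifnot(methods::is(unitSet, "ENAUnitSet"))
  keep <- !unitSet@units$empty
  nU <- unitSet@nU[keep, , drop = FALSE]
  units <- unitSet@units[keep, , drop = FALSE]
  if (nrow(nU) < 2) stop("need at least 2 non-empty units")
  center <- colMeans(nU)
  Xc <- sweep(nU, 2, center)
  if (max(abs(Xc)) < 1e-12)
    stop("degenerate space: all units identical")
  sv <- svd(Xc)
  d <- min(d, sum(sv$d > max(sv$d) * 1e-10))
  V <- sv$v[, seq_len(d), drop = FALSE]
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2, flip, "*")
  P <- Xc %*% V
  dimnames(V) <- list(codePairs(unitSet@set), paste0("SVD", seq_len(d)))
  colnames(P) <- colnames(V)
  varex <- sv$d^2 / sum(sv$d^2)
  space <- methods::new("ENASpace", set = unitSet@set,
                        pairNames = codePairs(unitSet@set),
                        center = center, loadings = V,
                        singularValues = sv$d,
                        varianceExplained = varex[seq_len(d)],
                        projections = P, units = units,
                        nodes = matrix(0, length(codeSet(unitSet@set)), d,
                                       dimnames = list(codeSet(unitSet@set),
                                                       colnames(V))),
                        nodeConstrained = stats::setNames(
                          rep(FALSE, length(codeSet(unitSet@set))),
                          codeSet(unitSet@set)),
                        positioningResidual = NA_real_)
  if (position) space <- positionNodes(space, unitSet)
  space
}

#' Position network nodes by least squares
#'
#' Places the code nodes so that each unit's network centroid -- the
#' edge-weight-weighted mean of edge-endpoint midpoints, with the unit's
#' normalised edge weights re-normalised to sum to one -- is as close as
#' possible to the unit's SVD projection: the positions minimise
#' \code{sum_i ||P_i - C_i||^2}. Because the centroid is linear in the node
#' coordinates this is an ordinary linear least-squares problem with a
#' closed-form solution. Codes that never co-occur are unconstrained; they
#' are flagged and placed at the origin.
#'
#' @param space an \linkS4class{ENASpace}.
#' @param unitSet the training \linkS4class{ENAUnitSet}.
#' @return The space with \code{nodes}, \code{nodeConstrained} and
#'   \code{positioningResidual} filled in.
#' @export
positionNodes <- function(space, unitSet) {
  keep <- !unitSet@units$empty
  nU <- unitSet@nU[keep, , drop = FALSE]
  M <- .centroidDesign(nU, space@set)
  P <- space@projections
  constrained <- colSums(abs(M)) > 0
  ## Minimum-norm least squares via the pseudoinverse. The design always
  ## has a null direction (translating instructor nodes by +c and worker
  ## nodes by -c leaves every cross-person edge midpoint average
  ## unchanged); the minimum-norm solution resolves it symmetrically and
  ## keeps the solution translation-equivariant in the projections.
  X <- matrix(0, ncol(M), ncol(P), dimnames = list(colnames(M), colnames(P)))
  Mc <- M[, constrained, drop = FALSE]
  sv <- svd(Mc)
  pos <- sv$d > max(sv$d) * 1e-10
  X[constrained, ] <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% P) / sv$d[pos])
  resid <- sum((P - M %*% X)^2)
  space@nodes <- X
  space@nodeConstrained <- stats::setNames(constrained, colnames(M))
  space@positioningResidual <- resid
  space
}

## Design matrix mapping node coordinates to unit network centroids:
## C_i = M_i %*% X with M_i[node] = 0.5 * sum of the unit's re-normalised
## edge weights over edges incident to the node.
.centroidDesign <- function(nU, set) {
  codes <- codeSet(set)
  nw <- .nWorkerCodes(set)
  W <- nU / pmax(rowSums(nU), .Machine$double.eps)
  M <- matrix(0, nrow(nU), length(codes), dimnames = list(NULL, codes))
  for (j in seq_len(ncol(nU))) {
    i <- (j - 1L) %/% nw + 1L        # instructor code of pair j
    w <- 4L + (j - 1L) %% nw + 1L    # worker code of pair j
    M[, i] <- M[, i] + 0.5 * W[, j]
    M[, w] <- M[, w] + 0.5 * W[, j]
  }
  M
}

## Network centroids of units under the node layout of a space.
.networkCentroids <- function(space, nU) {
  .centroidDesign(nU, space@set) %*% space@nodes
}

#' Project units into an existing ENA space
#'
#' Centers the units' normalised adjacency vectors with the space's training
#' mean and applies the kept loadings. Projecting the training units
#' reproduces their stored projections exactly.
#'
#' @param space an \linkS4class{ENASpace}.
#' @param x an \linkS4class{ENAUnitSet}, or a numeric matrix/vector of
#'   normalised adjacency rows on the space's pair basis.
#' @return Matrix of projections (units by kept dimensions).
#' @export
projectUnits <- function(space, x) {
  nU <- if (methods::is(x, "ENAUnitSet")) x@nU else
    if (is.matrix(x)) x else matrix(x, 1)
  sweep(nU, 2, space@center) %*% space@loadings
}
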