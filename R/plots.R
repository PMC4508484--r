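## Base-graphics visualisations of the ENA space, networks and curves.

.phaseColors <- function() {
  stats::setNames(grDevices::hcl.colors(5, "Dark 2"), .PHASES)
}

#' Plot an ENA space with unit points and phase mean centroids
#'
#' Unit projections are drawn as circles coloured by a grouping column of
#' the unit keys (default phase); group mean centroids as solid squares
#' surrounded by their 95\% confidence boxes; node positions as labelled
#' crosses.
#'
#' @param space an \linkS4class{ENASpace}.
#' @param unitSet the matching \linkS4class{ENAUnitSet}.
#' @param by grouping column (default \code{"phase"}).
#' @param main plot title.
#' @return Invisibly, the list of group summaries.
#' @export
plotSpace <- function(space, unitSet, by = "phase", main = "ENA space") {
  P <- space@projections
  units <- space@units
  lv <- unique(units[[by]])
  cols <- if (identical(sort(as.character(lv)), sort(.PHASES)))
    .phaseColors()[as.character(lv)]
  else stats::setNames(grDevices::hcl.colors(length(lv), "Dark 2"),
                       as.character(lv))
  graphics::plot(P[, 1], P[, 2], col = cols[as.character(units[[by]])],
                 pch = 1, xlab = colnames(P)[1], ylab = colnames(P)[2],
                 main = main, asp = 1)
  graphics::abline(h = 0, v = 0, col = "grey85")
  sums <- meanNetwork(space, unitSet, by = by)
  for (l in names(sums)) {
    g <- sums[[l]]
    graphics::points(g$centroid[1], g$centroid[2], pch = 15, cex = 1.4,
                     col = cols[l])
    if (!any(is.na(g$ciHalfWidth)))
      graphics::rect(g$centroid[1] - g$ciHalfWidth[1],
                     g$centroid[2] - g$ciHalfWidth[2],
                     g$centroid[1] + g$ciHalfWidth[1],
                     g$centroid[2] + g$ciHalfWidth[2], border = cols[l])
  }
  nd <- space@nodes
  graphics::points(nd[, 1], nd[, 2], pch = 4, col = "grey30")
  graphics::text(nd[, 1], nd[, 2], rownames(nd), pos = 3, cex = 0.7,
                 col = "grey30")
  graphics::legend("topright", legend = names(sums), col = cols[names(sums)],
                   pch = 15, cex = 0.7, bty = "n")
  invisible(sums)
}

#' Plot a (mean or difference) network over the node layout
#'
#' Edge width is proportional to the absolute edge weight; for difference
#' networks positive edges are drawn solid and negative edges dashed.
#'
#' @param space an \linkS4class{ENASpace} providing node positions.
#' @param edges named numeric vector over the space's code pairs.
#' @param main plot title.
#' @param scale width multiplier.
#' @return Invisibly, \code{NULL}.
#' @export
plotNetwork <- function(space, edges, main = "mean network", scale = 8) {
  nd <- space@nodes
  codes <- rownames(nd)
  nw <- .nWorkerCodes(space@set)
  graphics::plot(nd[, 1], nd[, 2], pch = 16, xlab = "", ylab = "",
                 main = main, asp = 1, col = "grey30")
  for (j in seq_along(edges)) {
    if (abs(edges[j]) < 1e-6) next
    i <- (j - 1L) %/% nw + 1L
    w <- 4L + (j - 1L) %% nw + 1L
    graphics::segments(nd[i, 1], nd[i, 2], nd[w, 1], nd[w, 2],
                       lwd = scale * abs(edges[j]),
                       lty = if (edges[j] >= 0) 1 else 2,
                       col = grDevices::adjustcolor(
                         if (edges[j] >= 0) "steelblue" else "firebrick",
                         0.7))
  }
  graphics::text(nd[, 1], nd[, 2], codes, pos = 3, cex = 0.7)
  invisible(NULL)
}

#' Plot alignment curves per phase
#'
#' @param x an \linkS4class{AlignmentCurveSet}.
#' @param main plot title.
#' @return Invisibly, the \code{\link{optimalLag}} table.
#' @export
plotAlignmentCurves <- function(x, main = "gaze alignment by lag") {
  cv <- curves(x)
  cols <- .phaseColors()
  graphics::plot(range(cv$lag_ms), range(cv$alignment, na.rm = TRUE),
                 type = "n", xlab = "lag (ms; positive = instructor leads)",
                 ylab = "alignment", main = main)
  for (p in unique(cv$phase)) {
    sub <- cv[cv$phase == p, ]
    graphics::lines(sub$lag_ms, sub$alignment, col = cols[p], lwd = 1.6)
  }
  ol <- optimalLag(x)
  graphics::points(ol$lag_ms, ol$alignment, col = cols[ol$phase], pch = 16)
  graphics::abline(v = 0, col = "grey85")
  graphics::legend("topright", legend = unique(cv$phase),
                   col = cols[unique(cv$phase)], lwd = 1.6, cex = 0.7,
                   bty = "n")
  invisible(ol)
}
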