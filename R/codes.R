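## Gaze-target categories, code sets and cross-person pair bases.
##
## Two code sets are used throughout:
##   * "gaze8": four gaze-target codes per role (Reference / Other / Target /
##     Person), the 8-node networks of the phase and repair analyses.
##   * "same6": the four instructor codes plus W.Same / W.Different, the
##     6-node networks of the lag-shifted alignment analysis.
## Edges only ever connect an instructor code to a worker code: one person
## cannot gaze at two targets in the same 50 ms segment, so within-role
## co-occurrence is impossible by construction.

.PHASES <- c("pre_reference", "reference", "post_reference", "action",
             "post_action")

.CATEGORIES <- c("Reference", "Other", "Target", "Person")

.SD_LEVELS <- c("Same", "Different")

## Reserved raw AOI labels (anything else is an ingredient identifier).
.AOI_TARGET   <- "target_bread"
.AOI_PARTNER  <- "partner"
.AOI_UNMAPPED <- "unmapped"

.ROLES <- c("instructor", "worker")

#' Gaze phase labels
#'
#' The five phases of a reference-action sequence, in temporal order:
#' pre-reference, reference, post-reference, action, post-action.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' gazePhases()
gazePhases <- function() .PHASES

#' Gaze-target categories
#'
#' The four role-relative gaze-target categories: \code{Reference} (the
#' ingredient referred to in the current sequence), \code{Other} (any other
#' ingredient), \code{Target} (the bread the ingredient is moved to) and
#' \code{Person} (the conversational partner). Unmapped gaze carries no
#' category.
#'
#' @return Character vector of length 4.
#' @export
gazeCategories <- function() .CATEGORIES

#' Code sets for the ENA analyses
#'
#' @param set \code{"gaze8"} for the eight role-by-category gaze codes used
#'   in the phase and repair analyses, or \code{"same6"} for the six codes
#'   (four instructor codes plus \code{W.Same}/\code{W.Different}) used in
#'   the lag-shifted alignment analysis.
#' @return Ordered character vector of code labels.
#' @export
#' @examples
#' codeSet("gaze8")
#' codeSet("same6")
codeSet <- function(set = c("gaze8", "same6")) {
  set <- match.arg(set)
  icodes <- paste0("I.Gaze_", .CATEGORIES)
  if (set == "gaze8") {
    c(icodes, paste0("W.Gaze_", .CATEGORIES))
  } else {
    c(icodes, "W.Same", "W.Different")
  }
}

#' Cross-person code pairs
#'
#' Enumerates the instructor-by-worker code pairs that index cumulative
#' adjacency vectors. Pair \code{(i, w)} maps to position
#' \code{(i - 1) * nW + w}, i.e. instructor-major order.
#'
#' @inheritParams codeSet
#' @return Character vector of pair labels, \code{"<I code> & <W code>"}.
#' @export
#' @examples
#' codePairs("same6")
codePairs <- function(set = c("gaze8", "same6")) {
  set <- match.arg(set)
  codes <- codeSet(set)
  icodes <- codes[1:4]
  wcodes <- codes[5:length(codes)]
  as.vector(t(outer(icodes, wcodes, paste, sep = " & ")))
}

.nWorkerCodes <- function(set) if (set == "gaze8") 4L else 2L

## Pair index from integer instructor / worker category codes (NA safe).
.pairIndex <- function(icat, wcat, set = "gaze8") {
  (icat - 1L) * .nWorkerCodes(set) + wcat
}

#' Map a raw AOI label to a role-relative gaze code
#'
#' Re-codes raw AOI labels relative to a sequence's referent: the referent
#' ingredient becomes \code{Reference}, \code{target_bread} becomes
#' \code{Target}, \code{partner} becomes \code{Person}, any other ingredient
#' becomes \code{Other}, and \code{unmapped} yields \code{NA} (no active
#' code). The same physical AOI can therefore be \code{Reference} in one
#' sequence and \code{Other} in the next.
#'
#' @param aoi Character vector of raw AOI labels.
#' @param role \code{"instructor"} or \code{"worker"} (recycled).
#' @param referent Referent ingredient identifier(s) (recycled).
#' @return Character vector of code labels (e.g. \code{"W.Gaze_Target"}),
#'   \code{NA} for unmapped gaze.
#' @export
#' @examples
#' mapGazeCode(c("ing_03", "target_bread", "unmapped"), "worker", "ing_03")
mapGazeCode <- function(aoi, role, referent) {
  role <- match.arg(role, .ROLES, several.ok = FALSE)
  cat <- .mapCategory(aoi, referent)
  prefix <- if (role == "instructor") "I.Gaze_" else "W.Gaze_"
  ifelse(is.na(cat), NA_character_, paste0(prefix, .CATEGORIES[cat]))
}

## Integer category (1..4, NA for unmapped), vectorised over aoi.
.mapCategory <- function(aoi, referent) {
  out <- rep.int(2L, length(aoi))             # default: Other (an ingredient)
  out[aoi == referent]       <- 1L
  out[aoi == .AOI_TARGET]    <- 3L
  out[aoi == .AOI_PARTNER]   <- 4L
  out[aoi == .AOI_UNMAPPED]  <- NA_integer_
  out
}
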