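## Delimited-text IO for fixation and sequence tables.
## TSV is the native format; .csv files are read/written comma-separated.

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.writeTable <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read an AOI fixation table
#'
#' Reads a delimited text table (TSV, or CSV by file extension) of
#' per-participant AOI-labelled fixations and validates the interval
#' invariants: positive duration and no overlap within one participant of
#' one interaction. Rows are returned sorted by participant and onset.
#'
#' @param path file with header columns \code{dyad_id}, \code{interaction_id},
#'   \code{role}, \code{t_start_ms}, \code{t_end_ms}, \code{aoi_raw}.
#' @return data.frame of validated fixations.
#' @seealso \code{\link{readGazeCorpus}}
#' @export
readFixations <- function(path) {
  fx <- .readTable(path)
  if (!all(.FIX_COLS %in% names(fx)))
    stop("missing fixation columns: ",
         paste(setdiff(.FIX_COLS, names(fx)), collapse = ", "))
  ## validity machinery of GazeCorpus does the interval checks
  corpus <- GazeCorpus(fx, .emptySequenceTable())
  fixations(corpus)
}

#' Read a reference-action-sequence table
#'
#' @param path file with header columns \code{dyad_id}, \code{interaction_id},
#'   \code{seq_index}, \code{referent_id}, \code{repair} (0/1),
#'   \code{reference_onset_ms} and \code{<phase>_start_ms} /
#'   \code{<phase>_end_ms} for the five phases.
#' @return data.frame of validated sequence annotations.
#' @export
readSequences <- function(path) {
  sq <- .readTable(path)
  need <- c(.SEQ_COLS, .seqPhaseCols())
  if (!all(need %in% names(sq)))
    stop("missing sequence columns: ",
         paste(setdiff(need, names(sq)), collapse = ", "))
  corpus <- GazeCorpus(.emptyFixationTable(), sq)
  sequences(corpus)
}

#' Read a full corpus from a fixation and a sequence table
#'
#' @param fixationPath,sequencePath paths passed to
#'   \code{\link{readFixations}} and \code{\link{readSequences}}.
#' @return A \linkS4class{GazeCorpus}.
#' @export
readGazeCorpus <- function(fixationPath, sequencePath) {
  GazeCorpus(readFixations(fixationPath), readSequences(sequencePath))
}

#' Write corpus tables
#'
#' Writes the fixation and sequence tables of a corpus as delimited text
#' (TSV, or CSV by extension). \code{repair} is written as 0/1. A write
#' followed by \code{\link{readGazeCorpus}} round-trips exactly.
#'
#' @param corpus a \linkS4class{GazeCorpus}.
#' @param fixationPath,sequencePath output paths.
#' @return Invisibly, the two paths.
#' @export
writeGazeCorpus <- function(corpus, fixationPath, sequencePath) {
  .writeTable(fixations(corpus), fixationPath)
  sq <- sequences(corpus)
  sq$repair <- as.integer(sq$repair)
  .writeTable(sq, sequencePath)
  invisible(c(fixationPath, sequencePath))
}

#' Export coded segments as a 0/1 indicator table
#'
#' One row per segment, one 0/1 column per code of the segment's code set,
#' preceded by the unit keys and segment midpoint.
#'
#' @param x a \linkS4class{CodedSegments}.
#' @param path output path (TSV, or CSV by extension).
#' @return Invisibly, the exported data.frame.
#' @export
exportSegments <- function(x, path) {
  s <- segments(x)
  ind <- segmentMatrix(x)
  out <- cbind(s[c("dyad_id", "interaction_id", "seq_index", "phase",
                   "t_mid_ms")], as.data.frame(ind, check.names = FALSE))
  .writeTable(out, path)
  invisible(out)
}

.emptyFixationTable <- function() {
  data.frame(dyad_id = character(), interaction_id = integer(),
             role = character(), t_start_ms = integer(),
             t_end_ms = integer(), aoi_raw = character(),
             stringsAsFactors = FALSE)
}

.emptySequenceTable <- function() {
  out <- data.frame(dyad_id = character(), interaction_id = integer(),
                    seq_index = integer(), referent_id = character(),
                    repair = logical(), reference_onset_ms = integer(),
                    stringsAsFactors = FALSE)
  for (cl in .seqPhaseCols()) out[[cl]] <- integer()
  out
}
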