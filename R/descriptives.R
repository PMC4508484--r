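## Descriptive statistics of a coded dyadic gaze corpus.

#' Descriptive gaze statistics
#'
#' Computes the summary statistics reported alongside the network analyses:
#' \itemize{
#'   \item \code{mutual_gaze_pct}: percentage of segments in which both
#'     participants gaze at each other (both codes \code{Gaze_Person}),
#'     among segments where both participants are AOI-mapped;
#'   \item \code{same_target_pct}: percentage of segments in which both
#'     participants' gaze maps to the same target category at zero lag,
#'     among segments where both are AOI-mapped;
#'   \item \code{instructor_lead_s}: mean latency (s) from the instructor's
#'     first referent fixation to reference onset;
#'   \item \code{worker_latency_s}: mean latency (s) from reference onset to
#'     the worker's first referent fixation at or after onset;
#'   \item \code{instructor_ref_fix_count}: mean number of instructor
#'     referent fixations before reference onset.
#' }
#' Fixation-level latencies use fixation onsets; sequences in which the
#' relevant fixation never occurs do not contribute. If the corpus lacks
#' reference-onset annotations (all \code{NA}) the latencies are reported
#' as \code{NA}.
#'
#' @param corpus a \linkS4class{GazeCorpus}.
#' @param coded optional pre-computed \code{\link{discretize}} output (the
#'   segment-level percentages are computed from it).
#' @param segmentMs segment length used when \code{coded} is missing.
#' @return Named list with the five statistics plus the per-sequence
#'   latency vectors (\code{worker_latency_by_seq_s}) and the number of
#'   contributing sequences.
#' @export
descriptiveStats <- function(corpus, coded = NULL, segmentMs = 50) {
  stopifnot(methods::is(corpus, "GazeCorpus"))
  if (is.null(coded)) coded <- discretize(corpus, segmentMs)
  s <- segments(coded)
  both <- !is.na(s$i_cat) & !is.na(s$w_cat)
  nboth <- sum(both)
  mutual <- if (nboth) 100 * sum(s$i_cat[both] == 4L & s$w_cat[both] == 4L) /
    nboth else NA_real_
  same <- if (nboth) 100 * sum(s$i_cat[both] == s$w_cat[both]) / nboth
    else NA_real_

  sq <- sequences(corpus)
  fx <- fixations(corpus)
  ilead <- wlat <- icount <- rep(NA_real_, nrow(sq))
  if (nrow(sq) && !all(is.na(sq$reference_onset_ms))) {
    fkey <- paste(fx$dyad_id, fx$interaction_id, fx$role, sep = "\r")
    fsplit <- split(seq_len(nrow(fx)), fkey)
    for (i in seq_len(nrow(sq))) {
      onset <- sq$reference_onset_ms[i]
      if (is.na(onset)) next
      s0 <- sq$pre_reference_start_ms[i]; s5 <- sq$post_action_end_ms[i]
      ref <- sq$referent_id[i]
      ii <- fsplit[[paste(sq$dyad_id[i], sq$interaction_id[i], "instructor",
                          sep = "\r")]]
      wi <- fsplit[[paste(sq$dyad_id[i], sq$interaction_id[i], "worker",
                          sep = "\r")]]
      if (length(ii)) {
        on <- fx$t_start_ms[ii]
        inref <- fx$aoi_raw[ii] == ref & on >= s0 & on < s5
        pre <- inref & on < onset
        icount[i] <- sum(pre)
        if (any(pre)) ilead[i] <- (onset - min(on[pre])) / 1000
      }
      if (length(wi)) {
        on <- fx$t_start_ms[wi]
        post <- fx$aoi_raw[wi] == ref & on >= onset & on < s5
        if (any(post)) wlat[i] <- (min(on[post]) - onset) / 1000
      }
    }
  }
  list(mutual_gaze_pct = mutual,
       same_target_pct = same,
       instructor_lead_s = .meanOrNA(ilead),
       worker_latency_s = .meanOrNA(wlat),
       instructor_ref_fix_count = .meanOrNA(icount),
       worker_latency_by_seq_s = wlat,
       n_segments_both_coded = nboth,
       n_sequences = nrow(sq))
}

.meanOrNA <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) mean(x) else NA_real_
}
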