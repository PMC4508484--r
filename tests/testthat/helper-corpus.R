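# Builders for small deterministic corpora used across test files.

# A sequence row with contiguous phase windows given by six boundaries
# (ms on the interaction clock).
seqRow <- function(dyad = "d01", interaction = 1L, seq_index = 1L,
                   referent = "ing_01", bounds, repair = FALSE) {
  stopifnot(length(bounds) == 6)
  row <- data.frame(dyad_id = dyad, interaction_id = interaction,
                    seq_index = seq_index, referent_id = referent,
                    repair = repair, reference_onset_ms = bounds[2],
                    stringsAsFactors = FALSE)
  for (p in 1:5) {
    row[[paste0(gazePhases()[p], "_start_ms")]] <- bounds[p]
    row[[paste0(gazePhases()[p], "_end_ms")]] <- bounds[p + 1]
  }
  row
}

fixRow <- function(dyad = "d01", interaction = 1L, role, start, end, aoi) {
  data.frame(dyad_id = dyad, interaction_id = interaction, role = role,
             t_start_ms = start, t_end_ms = end, aoi_raw = aoi,
             stringsAsFactors = FALSE)
}

# One-sequence corpus with explicit fixation streams. `ifix`/`wfix` are
# data.frames with columns start, end, aoi.
tinyCorpus <- function(ifix = NULL, wfix = NULL,
                       bounds = c(0, 500, 1000, 1500, 2000, 2500),
                       referent = "ing_01", repair = FALSE) {
  fx <- list()
  if (!is.null(ifix))
    fx <- c(fx, list(fixRow(role = "instructor", start = ifix$start,
                            end = ifix$end, aoi = ifix$aoi)))
  if (!is.null(wfix))
    fx <- c(fx, list(fixRow(role = "worker", start = wfix$start,
                            end = wfix$end, aoi = wfix$aoi)))
  fx <- if (length(fx)) do.call(rbind, fx) else
    fixRow(role = "instructor", start = 1, end = 2,
           aoi = "unmapped")[0, ]
  GazeCorpus(fx, seqRow(bounds = bounds, referent = referent,
                        repair = repair))
}

# Fixation stream tiling [from, to) with equal dwells and the given AOIs.
tiling <- function(aois, from = 0, dwell = 50) {
  n <- length(aois)
  data.frame(start = from + dwell * (seq_len(n) - 1),
             end = from + dwell * seq_len(n), aoi = aois,
             stringsAsFactors = FALSE)
}

# Small, fast synthetic configs.
fastConfig <- function(...) {
  modifyConfig(defaultGeneratorConfig(), ...)
}

# A config with identical per-phase behaviour (used as a chance-level /
# stationarity control): every phase draws from the same distributions,
# with no latency constraint and no repairs.
flatConfig <- function(rho = 0.35, leadMs = 0) {
  cfg <- defaultGeneratorConfig()
  id <- matrix(rep(cfg@instructorDist["action", ], each = 5), 5,
               dimnames = dimnames(cfg@instructorDist))
  wd <- matrix(rep(cfg@workerDist["action", ], each = 5), 5,
               dimnames = dimnames(cfg@workerDist))
  modifyConfig(cfg, instructorDist = id, workerDist = wd,
               rho = rep(rho, 5), leadMs = rep(leadMs, 5),
               workerLatencyMeanMs = NA_real_,
               instructorLeadMeanMs = NA_real_, repairProb = 0,
               repairWorkerDelta = cfg@repairWorkerDelta * 0,
               repairRhoFactor = rep(1, 5))
}
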