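## Synthetic dyadic gaze generator.
##
## The generator is a semi-Markov emulation of a five-phase reference-action
## sequence: phase durations are gamma, each participant's gaze is a renewal
## process of fixations with lognormal dwells and per-phase target
## distributions, and the worker is lag-coupled to the instructor. A coupled
## worker fixation adopts the instructor's AOI at (onset - lead) and stays
## on it until that source fixation ends, so with rho = 1 and lead = 0 the
## worker stream reproduces the instructor stream exactly. Two timing
## constraints shape referent gaze: the instructor first fixates the
## referent a configured lead before reference onset, and the worker first
## fixates it a configured latency after onset (earlier referent gaze,
## copied or marginal, is re-directed to another ingredient).

#' Construct a GeneratorConfig
#'
#' All arguments correspond to slots of \linkS4class{GeneratorConfig};
#' see that class for semantics and units. Distribution matrices may be
#' passed as phase-by-category matrices (rows
#' pre_reference..post_action, columns Reference, Other, Target, Person,
#' Unmapped).
#'
#' @param phaseDurationMeanS,phaseDurationCV gamma phase durations (s).
#' @param instructorDist,workerDist 5x5 gaze-target probability matrices.
#' @param rho,leadMs per-phase coupling probability and lead (ms).
#' @param dwellMeanMs,dwellCV lognormal dwell parameters, length-2
#'   (instructor, worker).
#' @param instructorLeadMeanMs,instructorLeadCV first-referent-fixation lead
#'   before reference onset (NA disables).
#' @param workerLatencyMeanMs,workerLatencyCV first-referent-fixation
#'   latency after reference onset (NA disables).
#' @param repairProb,repairWorkerDelta,repairRhoFactor repair-sequence
#'   perturbations.
#' @param nIngredients number of ingredient AOIs.
#' @param interSequenceGapMs gap between consecutive sequences (ms).
#' @param seed default seed (NA = use current RNG state).
#' @return A validated \linkS4class{GeneratorConfig}.
#' @seealso \code{\link{defaultGeneratorConfig}}, \code{\link{modifyConfig}}
#' @export
GeneratorConfig <- function(phaseDurationMeanS, phaseDurationCV = 0.4,
                            instructorDist, workerDist, rho, leadMs,
                            dwellMeanMs = c(instructor = 280, worker = 280),
                            dwellCV = c(instructor = 0.5, worker = 0.5),
                            instructorLeadMeanMs = NA_real_,
                            instructorLeadCV = 0.3,
                            workerLatencyMeanMs = NA_real_,
                            workerLatencyCV = 0.6,
                            repairProb = 0,
                            repairWorkerDelta = NULL,
                            repairRhoFactor = stats::setNames(rep(1, 5), .PHASES),
                            nIngredients = 23L,
                            interSequenceGapMs = 1000,
                            seed = NA_integer_) {
  nm5 <- function(x) stats::setNames(as.numeric(x), .PHASES)
  dist5 <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(.PHASES, .DIST_COLS)
    m
  }
  if (is.null(repairWorkerDelta))
    repairWorkerDelta <- matrix(0, 5, 5, dimnames = list(.PHASES, .DIST_COLS))
  methods::new("GeneratorConfig",
    phaseDurationMeanS = nm5(phaseDurationMeanS),
    phaseDurationCV = as.numeric(phaseDurationCV),
    instructorDist = dist5(instructorDist),
    workerDist = dist5(workerDist),
    rho = nm5(rho), leadMs = nm5(leadMs),
    dwellMeanMs = stats::setNames(as.numeric(dwellMeanMs),
                                  c("instructor", "worker")),
    dwellCV = stats::setNames(as.numeric(dwellCV),
                              c("instructor", "worker")),
    instructorLeadMeanMs = as.numeric(instructorLeadMeanMs),
    instructorLeadCV = as.numeric(instructorLeadCV),
    workerLatencyMeanMs = as.numeric(workerLatencyMeanMs),
    workerLatencyCV = as.numeric(workerLatencyCV),
    repairProb = as.numeric(repairProb),
    repairWorkerDelta = dist5(repairWorkerDelta),
    repairRhoFactor = nm5(repairRhoFactor),
    nIngredients = as.integer(nIngredients),
    interSequenceGapMs = as.numeric(interSequenceGapMs),
    seed = as.integer(seed))
}

#' The packaged default generator configuration
#'
#' Reads the calibrated default configuration shipped with the package
#' (\code{inst/extdata/default_config.json}). Its per-phase coupling leads
#' are the published optimal lags (0, 700, -300, -50, 300 ms), the phase
#' duration means are 1.90/1.32/0.78/1.68/0.81 s, and the per-phase target
#' distributions and coupling probabilities were tuned once, by closed-form
#' inversion of \code{\link{expectedAlignment}}, so that realised corpora
#' reproduce the published per-phase peak alignments, the 1.65 s worker
#' referent-fixation latency, the ~20\% unmapped-gaze fraction and the
#' overall shared-gaze proportion.
#'
#' @return A \linkS4class{GeneratorConfig}.
#' @export
#' @examples
#' cfg <- defaultGeneratorConfig()
#' cfg@leadMs
defaultGeneratorConfig <- function() {
  readGeneratorConfig(system.file("extdata", "default_config.json",
                                  package = "dyadENA", mustWork = TRUE))
}

#' Modify a GeneratorConfig
#'
#' Returns a copy of \code{config} with the named slots replaced and the
#' result re-validated.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param ... slot = value pairs (e.g. \code{rho = ...}).
#' @return A validated \linkS4class{GeneratorConfig}.
#' @export
modifyConfig <- function(config, ...) {
  args <- list(...)
  for (nm in names(args)) {
    cur <- methods::slot(config, nm)
    val <- args[[nm]]
    if (is.matrix(cur)) dimnames(val) <- dimnames(cur)
    else if (!is.null(names(cur)) && length(val) == length(cur))
      names(val) <- names(cur)
    methods::slot(config, nm) <- val
  }
  methods::validObject(config)
  config
}

#' Read / write generator configurations as JSON
#'
#' The JSON mirrors the \linkS4class{GeneratorConfig} slots; matrices are
#' stored as per-phase named rows.
#'
#' @param path JSON file path.
#' @return \code{readGeneratorConfig}: a \linkS4class{GeneratorConfig};
#'   \code{writeGeneratorConfig}: the path, invisibly.
#' @export
readGeneratorConfig <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(x) {
    m <- do.call(rbind, lapply(.PHASES, function(p) unlist(x[[p]])[.DIST_COLS]))
    dimnames(m) <- list(.PHASES, .DIST_COLS)
    m
  }
  GeneratorConfig(
    phaseDurationMeanS = unlist(js$phase_duration_mean_s)[.PHASES],
    phaseDurationCV = js$phase_duration_cv,
    instructorDist = mat(js$instructor_dist),
    workerDist = mat(js$worker_dist),
    rho = unlist(js$rho)[.PHASES],
    leadMs = unlist(js$lead_ms)[.PHASES],
    dwellMeanMs = unlist(js$dwell_mean_ms)[c("instructor", "worker")],
    dwellCV = unlist(js$dwell_cv)[c("instructor", "worker")],
    instructorLeadMeanMs = .jsNum(js$instructor_lead_mean_ms),
    instructorLeadCV = .jsNum(js$instructor_lead_cv),
    workerLatencyMeanMs = .jsNum(js$worker_latency_mean_ms),
    workerLatencyCV = .jsNum(js$worker_latency_cv),
    repairProb = js$repair_prob,
    repairWorkerDelta = mat(js$repair_worker_delta),
    repairRhoFactor = unlist(js$repair_rho_factor)[.PHASES],
    nIngredients = js$n_ingredients,
    interSequenceGapMs = js$inter_sequence_gap_ms,
    seed = if (is.null(js$seed)) NA_integer_ else js$seed)
}

.jsNum <- function(x) if (is.null(x) || !length(x)) NA_real_ else as.numeric(x)

.numOrNull <- function(x) if (is.na(x)) NULL else x

#' @rdname readGeneratorConfig
#' @param config a \linkS4class{GeneratorConfig} to serialise.
#' @export
writeGeneratorConfig <- function(config, path) {
  rows <- function(m) stats::setNames(
    lapply(.PHASES, function(p) as.list(m[p, ])), .PHASES)
  js <- list(
    phase_duration_mean_s = as.list(config@phaseDurationMeanS),
    phase_duration_cv = config@phaseDurationCV,
    instructor_dist = rows(config@instructorDist),
    worker_dist = rows(config@workerDist),
    rho = as.list(config@rho),
    lead_ms = as.list(config@leadMs),
    dwell_mean_ms = as.list(config@dwellMeanMs),
    dwell_cv = as.list(config@dwellCV),
    instructor_lead_mean_ms = .numOrNull(config@instructorLeadMeanMs),
    instructor_lead_cv = .numOrNull(config@instructorLeadCV),
    worker_latency_mean_ms = .numOrNull(config@workerLatencyMeanMs),
    worker_latency_cv = .numOrNull(config@workerLatencyCV),
    repair_prob = config@repairProb,
    repair_worker_delta = rows(config@repairWorkerDelta),
    repair_rho_factor = as.list(config@repairRhoFactor),
    n_ingredients = config@nIngredients,
    inter_sequence_gap_ms = config@interSequenceGapMs,
    seed = if (is.na(config@seed)) NULL else config@seed)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic dyadic gaze corpus
#'
#' Simulates \code{nDyads} dyads, each performing \code{nInteractions}
#' interactions of \code{nSequences} reference-action sequences, under the
#' stated generator configuration. The same seed always yields a
#' bit-identical corpus.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param nDyads,nInteractions,nSequences corpus dimensions (defaults mirror
#'   the study: 13 dyads, 2 interactions each, 15 sequences per interaction).
#' @param seed integer seed; defaults to the config's seed; NA leaves the
#'   session RNG state untouched.
#' @return A \linkS4class{GazeCorpus} with the config attached.
#' @export
#' @examples
#' corpus <- generateCorpus(defaultGeneratorConfig(), nDyads = 2,
#'                          nSequences = 3, seed = 7)
#' corpus
generateCorpus <- function(config, nDyads = 13L, nInteractions = 2L,
                           nSequences = 15L, seed = config@seed) {
  stopifnot(methods::is(config, "GeneratorConfig"),
            nDyads >= 1L, nSequences >= 1L)
  if (!is.na(seed)) set.seed(as.integer(seed))
  pre <- .precomputeConfig(config)
  fixl <- list(); seql <- list(); k <- 0L
  for (d in seq_len(nDyads)) {
    dyad <- sprintf("d%02d", d)
    for (it in seq_len(nInteractions)) {
      cursor <- 0
      for (s in seq_len(nSequences)) {
        referent <- pre$ingredients[sample.int(config@nIngredients, 1L)]
        repair <- stats::runif(1) < config@repairProb
        g <- .generateSequence(config, pre, referent, repair)
        k <- k + 1L
        off <- cursor
        g$ifix$t_start_ms <- g$ifix$t_start_ms + off
        g$ifix$t_end_ms <- g$ifix$t_end_ms + off
        g$wfix$t_start_ms <- g$wfix$t_start_ms + off
        g$wfix$t_end_ms <- g$wfix$t_end_ms + off
        fixl[[k]] <- data.frame(
          dyad_id = dyad, interaction_id = it,
          role = rep(c("instructor", "worker"),
                     c(nrow(g$ifix), nrow(g$wfix))),
          rbind(g$ifix[c("t_start_ms", "t_end_ms", "aoi_raw")],
                g$wfix[c("t_start_ms", "t_end_ms", "aoi_raw")]),
          stringsAsFactors = FALSE)
        b <- g$bounds + off
        row <- data.frame(dyad_id = dyad, interaction_id = it,
                          seq_index = s, referent_id = referent,
                          repair = repair, reference_onset_ms = b[2],
                          stringsAsFactors = FALSE)
        for (p in 1:5) {
          row[[paste0(.PHASES[p], "_start_ms")]] <- b[p]
          row[[paste0(.PHASES[p], "_end_ms")]] <- b[p + 1]
        }
        seql[[k]] <- row
        cursor <- b[6] + config@interSequenceGapMs
      }
    }
  }
  GazeCorpus(do.call(rbind, fixl), do.call(rbind, seql), config = config)
}

## Pre-computed sampling tables shared across sequences.
.precomputeConfig <- function(cfg) {
  cum <- function(m) {
    out <- t(apply(m, 1, cumsum))
    out[, 5] <- Inf                         # guard against rounding at 1
    out
  }
  noRef <- function(m) {                    # renormalised without Reference
    m[, 1] <- 0
    m / pmax(rowSums(m), .Machine$double.eps)
  }
  wrep <- cfg@workerDist + cfg@repairWorkerDelta
  list(ingredients = sprintf("ing_%02d", seq_len(cfg@nIngredients)),
       icum = cum(cfg@instructorDist),
       wcum = cum(cfg@workerDist),
       wcumRepair = cum(wrep),
       wcumNR = cum(noRef(cfg@workerDist)),
       wcumNRRepair = cum(noRef(wrep)),
       ilog = .lnormPars(cfg@dwellMeanMs["instructor"],
                         cfg@dwellCV["instructor"]),
       wlog = .lnormPars(cfg@dwellMeanMs["worker"], cfg@dwellCV["worker"]))
}

.lnormPars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.gammaDraw <- function(n, mean, cv) {
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

## One reference-action sequence on the local clock [0, T).
.generateSequence <- function(cfg, pre, referent, repair) {
  durs <- pmax(.gammaDraw(5, cfg@phaseDurationMeanS * 1000,
                          cfg@phaseDurationCV), 200)
  bounds <- c(0, cumsum(round(durs)))
  T_ <- bounds[6]; onset <- bounds[2]

  ## --- instructor stream ---
  tLead <- NA_real_
  if (!is.na(cfg@instructorLeadMeanMs)) {
    lead <- .gammaDraw(1, cfg@instructorLeadMeanMs, cfg@instructorLeadCV)
    tLead <- max(onset - lead, 0)
  }
  ifx <- .renewalFixations(T_, pre$ilog, forceT = tLead)
  mid <- (ifx$start + ifx$end) / 2
  ph <- pmin(pmax(findInterval(mid, bounds[2:5]) + 1L, 1L), 5L)
  u <- stats::runif(nrow(ifx))
  icat <- max.col(u <= pre$icum[ph, , drop = FALSE], "first")
  icat[ifx$forced] <- 1L
  ## lead censor: early referent glances count as unmappable scanning
  if (!is.na(tLead)) icat[icat == 1L & ifx$start < tLead & !ifx$forced] <- 5L
  iaoi <- .realizeAOI(icat, referent, pre$ingredients)

  ## --- worker stream (sequential; coupling looks up the instructor) ---
  rho <- cfg@rho * if (repair) cfg@repairRhoFactor else 1
  wcum <- if (repair) pre$wcumRepair else pre$wcum
  wcumNR <- if (repair) pre$wcumNRRepair else pre$wcumNR
  tW <- NA_real_
  if (!is.na(cfg@workerLatencyMeanMs)) {
    L <- .gammaDraw(1, cfg@workerLatencyMeanMs, cfg@workerLatencyCV)
    tW <- min(onset + L, T_ - 100)
    tW <- max(tW, onset + 1)
  }
  cap <- ceiling(T_ / 40) + 12L
  wst <- wen <- numeric(cap); waoi <- character(cap)
  n <- 0L; t <- 0; forcedDone <- is.na(tW)
  while (t < T_) {
    if (!forcedDone && t >= tW) {            # forced first referent fixation
      dur <- stats::rlnorm(1, pre$wlog[1], pre$wlog[2])
      aoi <- referent
      forcedDone <- TRUE
    } else {
      phw <- min(max(findInterval(t, bounds[2:5]) + 1L, 1L), 5L)
      src <- t - cfg@leadMs[phw]
      coupled <- stats::runif(1) < rho[phw] && src >= 0 && src < T_
      if (coupled) {
        j <- findInterval(src, ifx$start)
        aoi <- iaoi[j]
        ## synchronised copying: stay on the source target until the source
        ## fixation ends (shifted by the lead)
        dur <- max(ifx$end[j] + cfg@leadMs[phw] - t, 1)
        ## latency censor: followed gaze cannot land on the not-yet-known
        ## referent; it settles on a neighbouring ingredient instead
        if (!forcedDone && aoi == referent)
          aoi <- .otherIngredient(referent, pre$ingredients)
      } else {
        u1 <- stats::runif(1)
        ## before the referent is identified, marginal gaze simply avoids
        ## it: redraw from the remaining categories
        cum <- if (forcedDone) wcum[phw, ] else wcumNR[phw, ]
        cat <- which(u1 <= cum)[1]
        aoi <- .realizeAOI(cat, referent, pre$ingredients)
        dur <- stats::rlnorm(1, pre$wlog[1], pre$wlog[2])
      }
      ## gaze decisions are re-taken at phase boundaries (verbal/physical
      ## events), so a fixation's coupling lag is always its phase's own
      dur <- min(dur, bounds[phw + 1] - t)
      if (!forcedDone && t + dur > tW) dur <- tW - t   # truncate at force
    }
    if (dur >= 1) {
      n <- n + 1L
      if (n > length(wst)) {                  # grow (rare)
        wst <- c(wst, numeric(cap)); wen <- c(wen, numeric(cap))
        waoi <- c(waoi, character(cap))
      }
      wst[n] <- t; wen[n] <- min(t + dur, T_); waoi[n] <- aoi
    }
    t <- t + max(dur, 1)
  }
  wfx <- data.frame(start = wst[seq_len(n)], end = wen[seq_len(n)],
                    aoi_raw = waoi[seq_len(n)], stringsAsFactors = FALSE)

  list(ifix = .roundFix(ifx$start, ifx$end, iaoi),
       wfix = .roundFix(wfx$start, wfx$end, wfx$aoi_raw),
       bounds = bounds)
}

## Renewal fixation boundaries on [0, T), optionally with a fixation forced
## to start at forceT (the covering fixation is truncated there).
.renewalFixations <- function(T_, logpars, forceT = NA_real_) {
  draw <- function(from, to) {
    if (from >= to) return(NULL)
    need <- ceiling((to - from) / exp(logpars[1])) + 10L
    repeat {
      d <- stats::rlnorm(need, logpars[1], logpars[2])
      b <- from + cumsum(d)
      if (b[length(b)] >= to) break
      need <- need * 2L
    }
    keep <- seq_len(which(b >= to)[1])
    st <- c(from, b[keep][-length(keep)])
    data.frame(start = st, end = pmin(b[keep], to))
  }
  if (is.na(forceT) || forceT <= 0) {
    out <- draw(0, T_)
    out$forced <- FALSE
    if (!is.na(forceT) && forceT <= 0 && nrow(out)) out$forced[1] <- TRUE
    return(out)
  }
  head_ <- draw(0, forceT)
  fdur <- stats::rlnorm(1, logpars[1], logpars[2])
  fend <- min(forceT + fdur, T_)
  forced <- data.frame(start = forceT, end = fend)
  tail_ <- draw(fend, T_)
  out <- rbind(head_, forced, tail_)
  out$forced <- FALSE
  out$forced[nrow(head_) + 1L] <- TRUE
  out
}

.realizeAOI <- function(cat, referent, ingredients) {
  out <- character(length(cat))
  out[cat == 1L] <- referent
  out[cat == 3L] <- .AOI_TARGET
  out[cat == 4L] <- .AOI_PARTNER
  out[cat == 5L] <- .AOI_UNMAPPED
  oth <- which(cat == 2L)
  if (length(oth))
    out[oth] <- vapply(oth, function(i)
      .otherIngredient(referent, ingredients), character(1))
  out
}

.otherIngredient <- function(referent, ingredients) {
  pool <- ingredients[ingredients != referent]
  pool[sample.int(length(pool), 1L)]
}

## Round fixation boundaries to integer ms, preserving contiguity.
.roundFix <- function(start, end, aoi) {
  st <- round(start); en <- round(end)
  keep <- en > st
  data.frame(t_start_ms = st[keep], t_end_ms = en[keep],
             aoi_raw = aoi[keep], stringsAsFactors = FALSE)
}
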