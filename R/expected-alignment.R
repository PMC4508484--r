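## Closed-form expected gaze alignment under the generator model.
##
## At the coupling lead the expected alignment is the spec'd
## rho * (coded mass) + (1 - rho) * (marginal match) form; away from the
## lead the copy branch decays with the probability that the instructor's
## fixation covering the copy source also covers the comparison time. For a
## stationary renewal process with dwell distribution D that probability at
## separation 'delta' is E[(D - delta)+] / E[D], available in closed form
## for the lognormal. Two generator constraints are folded in as first-order
## corrections (exact quadrature over the gamma duration/latency laws,
## moment-matched gamma for duration sums):
##   * the worker referent-latency censor re-directs referent gaze to
##     another ingredient before onset + latency, and inserts a forced
##     referent fixation at that moment;
##   * the instructor first-referent-lead censor removes early referent
##     gaze in the pre-reference phase and inserts a forced fixation.
## Cross-phase leakage of the lagged time is handled by mixing the phase
## target distributions in proportion to mean-duration window overlaps.

## P(fixation covering t also covers t + delta), stationary lognormal renewal
.overlapKernel <- function(delta, meanMs, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(meanMs) - sdlog^2 / 2
  ed <- meanMs
  delta <- abs(delta)
  out <- numeric(length(delta))
  z <- delta > 0
  d1 <- (meanlog + sdlog^2 - log(delta[z])) / sdlog
  d2 <- (meanlog - log(delta[z])) / sdlog
  out[z] <- pmax((ed * stats::pnorm(d1) - delta[z] * stats::pnorm(d2)) / ed, 0)
  out[!z] <- 1
  out
}

.gammaGrid <- function(mean, cv, n = 32) {
  shape <- 1 / cv^2
  stats::qgamma((seq_len(n) - 0.5) / n, shape = shape, scale = mean / shape)
}

## Moment-matched gamma grid for a sum of independent gamma durations.
.gammaSumGrid <- function(means, cv, n = 32) {
  if (!length(means)) return(0)
  mu <- sum(means)
  va <- sum((means * cv)^2)
  .gammaGrid(mu, sqrt(va) / mu, n)
}

## Worker-censor geometry: per-phase censored time fraction and the
## distribution of the forced referent fixation over phases.
.censorModel <- function(cfg) {
  if (is.na(cfg@workerLatencyMeanMs))
    return(list(cens = stats::setNames(rep(0, 5), .PHASES),
                forceP = stats::setNames(rep(0, 5), .PHASES)))
  dm <- cfg@phaseDurationMeanS * 1000
  cv <- cfg@phaseDurationCV
  L <- .gammaGrid(cfg@workerLatencyMeanMs, cfg@workerLatencyCV)
  cens <- forceP <- stats::setNames(numeric(5), .PHASES)
  cens[1] <- 1                     # no referent gaze before onset at all
  for (p in 2:5) {
    S <- .gammaSumGrid(dm[seq(2, length.out = p - 2)], cv)   # onset..start
    D <- .gammaGrid(dm[p], cv, n = 24)
    X <- as.vector(pmax(outer(L, S, "-"), 0))       # censor time past start
    cens[p] <- mean(outer(X, D, pmin)) / mean(D)
    forceP[p] <- mean(outer(X, D, function(x, d) x > 0 & x < d))
  }
  list(cens = cens, forceP = forceP)
}

## Effective instructor target distributions after the first-referent-lead
## constraint (pre-reference phase only).
.effInstructorDist <- function(cfg) {
  p <- cfg@instructorDist
  if (is.na(cfg@instructorLeadMeanMs)) return(p)
  lead <- .gammaGrid(cfg@instructorLeadMeanMs, cfg@instructorLeadCV)
  D1 <- .gammaGrid(cfg@phaseDurationMeanS[1] * 1000, cfg@phaseDurationCV,
                   n = 24)
  fa <- mean(pmin(rep(lead, times = length(D1)),
                  rep(D1, each = length(lead))) /
             rep(D1, each = length(lead)))        # allowed (late) fraction
  fF <- min(cfg@dwellMeanMs["instructor"] / (cfg@phaseDurationMeanS[1] * 1000),
            fa * 0.9)                              # forced fixation share
  row <- p[1, ]
  cens <- (1 - fa) * row                 # early part: referent -> unmapped
  cens["Unmapped"] <- cens["Unmapped"] + cens["Reference"]
  cens["Reference"] <- 0
  eff <- cens + fF * c(1, 0, 0, 0, 0) + (fa - fF) * row
  p[1, ] <- eff / sum(eff)
  p
}

## Per-decision coupling probability -> expected fraction of worker
## *segments* covered by coupled fixations. Coupled fixations last the
## residual of the instructor source fixation (length-biased mean
## E[D](1+cv^2)/2), uncoupled ones a full worker dwell, so the time share
## of coupling is below rho.
.segmentShare <- function(cfg, rho) {
  ## a coupled fixation lasts the residual of its source fixation
  ## (length-biased mean E[D](1+cv^2)/2). Runs of consecutive coupled
  ## fixations last longer than this, so the share is a slight
  ## underestimate at high rho; the peak of the curve, where calibration
  ## anchors, is insensitive to it.
  rC <- cfg@dwellMeanMs["instructor"] *
    (1 + cfg@dwellCV["instructor"]^2) / 2
  rM <- cfg@dwellMeanMs["worker"]
  unname(rho * rC / (rho * rC + (1 - rho) * rM))
}

## Worker marginal distribution under the latency censor: referent draws
## are re-taken from the remaining categories for the censored fraction of
## the phase.
.censoredMarginal <- function(q, cens) {
  if (cens <= 0 || q["Reference"] <= 0) return(q)
  redist <- q
  redist["Reference"] <- 0
  redist <- redist / sum(redist)
  (1 - cens) * q + cens * redist
}

## Overlap of phase 'phase' shifted by -lagMs with each phase's
## mean-duration window; 'out' = mass falling outside the sequence.
.phaseMixture <- function(cfg, phase, lagMs) {
  dm <- cfg@phaseDurationMeanS * 1000
  b <- c(0, cumsum(dm))
  i <- match(phase, .PHASES)
  a <- b[i] - lagMs; z <- b[i + 1] - lagMs
  wgt <- pmax(pmin(z, b[-1]) - pmax(a, b[-6]), 0)
  out <- (z - a) - sum(wgt)
  list(w = wgt / (z - a), out = out / (z - a))
}

#' Expected gaze alignment at a time lag
#'
#' Closed-form expected same-target probability (both participants
#' AOI-mapped, denominator all timeline-valid segment pairs) for a phase of
#' the generator model, as a function of the scan lag. At the configured
#' coupling lead this reduces to
#' \code{rho * (mapped mass) + (1 - rho) * sum_k p_k q_k}; away from it the
#' coupled term decays with the dwell overlap kernel. Used to calibrate the
#' default configuration against the published per-phase alignment
#' percentages, and as an oracle for the realised alignment curves.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param phase one of \code{gazePhases()}.
#' @param lagMs numeric vector of lags in ms (positive = instructor leads).
#' @return Numeric vector of expected alignment fractions in [0, 1].
#' @seealso \code{\link{alignmentCurves}}, \code{\link{defaultGeneratorConfig}}
#' @export
#' @examples
#' cfg <- defaultGeneratorConfig()
#' expectedAlignment(cfg, "post_reference", cfg@leadMs["post_reference"])
expectedAlignment <- function(config, phase, lagMs) {
  phase <- match.arg(phase, .PHASES)
  i <- match(phase, .PHASES)
  pEff <- .effInstructorDist(config)
  cm <- .censorModel(config)
  lam <- config@leadMs[i]
  rho <- config@rho[i]
  cens <- cm$cens[i]
  fFW <- if (is.na(config@workerLatencyMeanMs)) 0 else
    min(cm$forceP[i] * config@dwellMeanMs["worker"] /
          (config@phaseDurationMeanS[i] * 1000), 0.5)

  srcMix <- .phaseMixture(config, phase, lam)
  pSrc <- drop(srcMix$w %*% pEff)
  rhoEff <- .segmentShare(config, rho * (1 - srcMix$out))
  qShown <- .censoredMarginal(config@workerDist[i, ], cens)
  shownSrc <- pSrc + cens * pSrc["Reference"] *
    c(-1, 1, 0, 0, 0)                     # censored copies settle on Other

  vapply(lagMs, function(tau) {
    cmpMix <- .phaseMixture(config, phase, tau)
    pCmp <- drop(cmpMix$w %*% pEff)
    if (sum(cmpMix$w) <= 0) return(NA_real_)
    pCmp <- pCmp / sum(cmpMix$w)            # condition on valid comparison
    w <- .overlapKernel(tau - lam, config@dwellMeanMs["instructor"],
                        config@dwellCV["instructor"])
    M1 <- (1 - pSrc["Unmapped"]) - cens * pSrc["Reference"]
    M2 <- sum(shownSrc[1:4] * pCmp[1:4])
    M3 <- sum(qShown[1:4] * pCmp[1:4])
    unname(fFW * pCmp["Reference"] +
           (1 - fFW) * (rhoEff * (w * M1 + (1 - w) * M2) +
                        (1 - rhoEff) * M3))
  }, numeric(1))
}

## Expected probability that both participants are AOI-mapped in a segment
## of the given phase (zero lag), same approximation stack as
## expectedAlignment.
.expectedBothCoded <- function(config, phase) {
  i <- match(phase, .PHASES)
  pEff <- .effInstructorDist(config)
  cm <- .censorModel(config)
  lam <- config@leadMs[i]
  rho <- config@rho[i]
  fFW <- if (is.na(config@workerLatencyMeanMs)) 0 else
    min(cm$forceP[i] * config@dwellMeanMs["worker"] /
          (config@phaseDurationMeanS[i] * 1000), 0.5)
  srcMix <- .phaseMixture(config, phase, lam)
  pSrc <- drop(srcMix$w %*% pEff)
  rhoEff <- .segmentShare(config, rho * (1 - srcMix$out))
  p0 <- pEff[i, ]
  cens <- cm$cens[i]
  wCodedCopy <- 1 - pSrc["Unmapped"]    # censored copies stay coded (Other)
  wCodedMarg <- 1 - .censoredMarginal(config@workerDist[i, ],
                                      cens)["Unmapped"]
  w0 <- .overlapKernel(lam, config@dwellMeanMs["instructor"],
                       config@dwellCV["instructor"])
  unname(fFW * (1 - p0["Unmapped"]) +
         (1 - fFW) * (rhoEff * (w0 * wCodedCopy +
                                (1 - w0) * wCodedCopy *
                                  (1 - p0["Unmapped"])) +
                      (1 - rhoEff) * (1 - p0["Unmapped"]) * wCodedMarg))
}

## Expected whole-sequence shared-gaze percentage (same target at zero lag,
## among segments with both participants mapped), duration-weighted over
## phases. Calibration helper for the packaged defaults.
.expectedSharedGazePct <- function(config) {
  dm <- config@phaseDurationMeanS
  num <- sum(dm * vapply(.PHASES, function(p)
    expectedAlignment(config, p, 0), numeric(1)))
  den <- sum(dm * vapply(.PHASES, function(p)
    .expectedBothCoded(config, p), numeric(1)))
  100 * num / den
}
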