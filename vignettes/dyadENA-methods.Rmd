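---
title: "Modelling dyadic gaze coordination with dyadENA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dyadic gaze coordination with dyadENA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadENA)
```

## 1. The data and the coding model

`dyadENA` analyses dual eye-tracking recordings of instructor–worker
dyads collaborating over a shared workspace. The atomic input is the
*fixation*: a half-open interval `[t_start, t_end)` in integer
milliseconds on the interaction's shared clock, labelled with a raw AOI
(an ingredient identifier, `target_bread`, `partner`, or `unmapped`).
Each interaction is annotated with *reference-action sequences*, five
contiguous phases each: pre-reference, reference, post-reference, action
and post-action, plus the referent's identity and a repair flag.

Codes are *sequence-relative*: within a sequence the referent ingredient
maps to `Gaze_Reference`, every other ingredient to `Gaze_Other`, the
bread to `Gaze_Target` and the partner to `Gaze_Person`, per role. The
same physical AOI can therefore be `Reference` in one sequence and
`Other` in the next. Unmapped gaze activates no code.

Discretisation tiles each sequence with 50 ms segments anchored at the
sequence start (phases then tile cleanly, because they are contiguous).
A segment carries, per participant, the code of the fixation covering its
*midpoint* — an unambiguous rule that guarantees at most one active code
per participant; majority-overlap coding would need a tie rule of its
own. A fixation ending exactly at a midpoint does not cover it (half-open
convention). Segments between sequences are not coded at all: whether the
original analyses coded inter-sequence gaps is unknowable from the
published material, and every analysis here is conditioned on being
inside a sequence.

## 2. The ENA core

For a unit of analysis (by default dyad-interaction × phase, optionally ×
repair) the coded segments accumulate into a cumulative adjacency vector
over the 16 (or 8, see §4) cross-person code pairs: `U_j` counts the
segments in which both codes of pair `j` are active. Only
instructor × worker pairs exist — one person cannot gaze at two targets
in the same segment. `U` is normalised to the unit hypersphere,
`nU = U/‖U‖₂`, to control for unit length; all-zero units are flagged and
excluded from spaces.

The normalised vectors are centered on their grand mean and decomposed by
SVD; the top `d = 2` dimensions are kept, giving unit projections `P_i`.
Whether the original method centered before the SVD is not documented; we
center so that the origin is the data mean and projections average to
zero, which makes centroid comparisons translation-free. Sign
indeterminacy is resolved deterministically (each loading's
largest-magnitude entry is positive); axis orientation may therefore
mirror published figures, and nothing downstream depends on it.

**Node positioning.** Nodes (codes) are placed by minimising
`Σ_i ‖P_i − C_i‖²`, where the network centroid `C_i` is defined as the
edge-weight-weighted mean of edge-endpoint midpoints, with the unit's
`nU` weights renormalised to sum to one. This definition makes `C_i`
*linear* in the node coordinates, so positioning is an ordinary linear
least-squares problem with a closed-form solution — no iterative
optimiser, no local minima. Two structural facts matter:

* the design is always rank-deficient by one: translating all instructor
  nodes by `+c` and all worker nodes by `−c` leaves every cross-person
  edge midpoint unchanged. We return the minimum-norm (pseudoinverse)
  solution, which resolves this symmetrically and makes the layout
  exactly translation-equivariant in the projections;
* codes that never co-occur are unconstrained; they are flagged
  (`nodeConstrained`) and placed at the origin.

Group summaries are exact arithmetic: the mean network is the per-edge
mean of member `nU` (so partition means recombine, weighted by part
sizes), the group centroid is the mean of member projections, and 95%
confidence half-widths are t-based (`qt(0.975, n−1)·sd/√n`); a
standard-error variant is a trivial rescaling. Group comparisons use
Student's pooled-variance t-test on one kept dimension (matching the
published analysis; Welch via `varEqual = FALSE`) with Cohen's d from the
pooled SD.

## 3. Lag alignment

`alignmentCurves()` scans lags τ from −2000 to 2000 ms in 50 ms steps.
For each phase, alignment(τ) is the fraction of phase segments `t`
(pooled over dyads and sequences) whose worker code equals the
instructor code at `t − τ`, with both participants AOI-mapped; positive τ
puts the instructor ahead. Two conventions need fixing because the
source material is ambiguous:

* **Denominator.** The denominator counts *every* timeline-valid segment
  pair — segments with unmapped gaze stay in the denominator but cannot
  match. This is the only reading under which the published per-phase
  peak alignments (22.5–36.1%) and the published whole-sequence
  shared-gaze proportion (31.16%, a *conditional* proportion among
  both-mapped segments, reported by `descriptiveStats`) are jointly
  attainable: the duration-weighted mean of the *peak* alignments is
  28.9%, and zero-lag alignment cannot exceed the peak, so 31.16% cannot
  share the peaks' denominator.
* **Comparisons never straddle sequence boundaries**; a shifted partner
  outside the sequence leaves the denominator.

`optimalLag()` takes the argmax, breaking ties (within 1e-9) toward the
smallest |τ| and then toward positive τ, and warns on flat curves. Lags
whose denominator falls below `max(20, 5%)` of the phase's maximum are
excluded from the peak search: at extreme lags only a handful of
unusually long phase occurrences remain comparable and their fraction is
noise. "Same target" matches on the four-way code category (two different
non-referent ingredients both count as `Other`), following the published
code definitions; raw-AOI matching would only lower chance alignment.

The shifted analysis moves each phase's worker stream by that phase's
optimal lag on the segment grid, recodes the worker as `W.Same` /
`W.Different` (active only when both participants are mapped), and runs
the full ENA pipeline on the resulting 6-code, 8-pair basis.

## 4. Phase prediction

`looSpace()` rebuilds the space without one dyad; `sampleWindows()` draws
fixed-length windows uniformly over admissible (sequence, phase, start)
positions, entirely inside a single phase occurrence (the published
procedure does not say how straddling windows were handled; excluding
them is the only choice that keeps labels unambiguous). Windows are
accumulated, normalised, centered with the *training* mean, projected,
and labelled by the nearest phase centroid (Euclidean, in the kept 2-D
space, matching the visual argument of the published figures); windows
with no co-occurrence at all are "uncodable" and tallied separately. The
number of windows per phase is a free parameter (default 50) — the
published confusion matrix has uneven, unexplained row sums which we do
not attempt to match.

## 5. The synthetic generator and its calibration

The generator emulates the statistical structure the analyses assume —
it is a *stated world*, not a fit to raw data (which is not available):

* phase durations: gamma with the published means
  (1.90/1.32/0.78/1.68/0.81 s) and CV 0.4 (the publication gives only
  means; 0.4 gives realistic spread without degenerate sub-200 ms phases,
  which are floored);
* fixations: renewal processes with lognormal dwells (means 280 ms
  instructor / 240 ms worker, CV 0.5 — typical task-driven fixation
  scales); per-phase gaze-target categoricals including an Unmapped mass;
* coupling: with per-phase probability ρ a worker fixation *copies* the
  instructor's AOI at lag λ (λ > 0 = instructor leads) and stays on it
  until that source fixation ends, re-deciding at phase boundaries. With
  ρ = 1 and λ = 0 the worker stream reproduces the instructor's exactly.
  Copy runs, not per-segment coin flips, produce realistic dwell runs;
* the worker's first referent fixation is censored before
  onset + latency (gamma, mean 1.69 s, CV 0.6, calibrated so the realised
  mean latency is the published 1.65 s): marginal referent draws re-draw
  from the remaining categories, *copied* referent hits settle on a
  neighbouring ingredient (the worker follows the instructor's gaze into
  the ingredient cluster but cannot single out the yet-unnamed referent).
  A forced referent fixation is inserted at onset + latency. This
  mechanism is what produces the strong pre-reference
  `I.Gaze_Reference–W.Gaze_Other` edge of the published mean networks;
* an analogous instructor first-referent-lead constraint is implemented
  (`instructorLeadMeanMs`) but *disabled in the defaults*: with the
  chosen pre-reference distribution the instructor's referent-lead
  statistics emerge from the renewal process itself, and the censor's
  side effects (inflating early pre-reference `Other`/unmapped mass)
  degrade the pre-reference alignment calibration. The realised lead
  (~1.5 s) and referent-fixation count (~2.4) sit somewhat above the
  published 1.31 s / 1.93;
* repair sequences (probability 0.25; the publication does not report a
  rate) perturb the *worker*: pre-reference marginal mass moves from
  `Other` to `Target` (worker lingering on the bread), reference and
  post-reference mass moves toward `Other` with post-reference referent
  mass and coupling reduced — the three directions the repair analysis
  reports.

**Calibration.** `expectedAlignment()` gives the closed-form expected
alignment: at the lead it is exactly
`ρ·(mapped mass) + (1−ρ)·Σ_k p_k q_k`; away from the lead the coupled
term decays with the dwell overlap kernel `E[(D−Δ)₊]/E[D]` (lognormal
partial expectation), and first-order corrections account for the
latency censor, the coupled time-share (coupled fixations last the
source's residual), forced fixations, and cross-phase leakage of the
lagged time (mean-duration window mixing). Per-phase ρ was solved once
by inverting this closed form at the published per-phase alignments,
then polished with two damped fixed-point corrections against realised
corpora; the result is frozen in
`inst/extdata/default_config.json`. Accuracy of the closed form is a few
hundredths off the peak (it underestimates long coupled runs), which is
why the realised-feedback step exists.

Three tensions could not be resolved exactly and were decided once:

* the published whole-sequence shared-gaze figure and the per-phase peak
  alignments are only jointly attainable with slightly lower unmapped
  mass than the published ~20%; realised mapped fractions are ~83%
  (instructor) and ~86% (worker) against the published 79.5/81.7%;
* the post-action coupling is floored at ρ = 0.36, above the value that
  would match the published 27.0% post-action alignment (realised ~38%):
  the published peak is too shallow for its 300 ms lag to be identifiable
  from a 200-sequence corpus, and the lag, not the height, is the
  reproduced quantity;
* at the 200-sequence scale the pre- and post-reference peak alignments
  carry ±1.5–2 percentage points of Monte-Carlo noise; calibration
  centers them on the published values but individual corpora scatter.

What a green test does **not** establish: the generator has a single
shared clock with no tracker noise, drift, blinks or missing data; no
verbal content, pointing or kinematics; mutual-gaze dynamics beyond a
`Person` category are absent; repair is a sequence-level flag without
clarification sub-phases. Conclusions about real recordings need the
real recordings.

## 6. Numerical and statistical caveats

* **Sphere-normalisation small-sample bias.** Units that pool few
  segments have noisier counts, and `U/‖U‖₂` then systematically shrinks
  dominant edges relative to units pooling many segments. In the repair
  analysis the repair stratum pools ~4× fewer sequences, so *differences
  of normalised mean networks* partly reflect unit size, not behaviour.
  The package still reports the ENA-standard normalised difference
  network, but directional checks in the test-suite use pooled raw edge
  shares (`ΣU / ‖ΣU‖₁` per stratum), which are unbiased under unequal
  unit sizes. Users comparing strata of very different sizes should do
  the same.
* The repair t-tests treat the two interactions of a dyad as independent
  units (mirroring the published n = 26); the dependence caveat carries
  over. No multiple-testing correction is applied across phases by
  default (`bonferroni = TRUE` is available).
* Pooled-segment lag curves (default) weight dyads by their data volume;
  per-dyad averaging would weight dyads equally but is noisier for short
  phases.
* All randomness funnels through R's RNG: the same seed yields
  bit-identical corpora, analyses and artefacts.

```{r example, eval = FALSE}
cfg    <- defaultGeneratorConfig()
corpus <- generateCorpus(cfg, nDyads = 13, nInteractions = 2,
                         nSequences = 15, seed = 1)
coded  <- discretize(corpus)
space  <- buildSpace(accumulateUnits(coded))
plotSpace(space, accumulateUnits(coded))
optimalLag(alignmentCurves(coded))
repairReport(corpus, coded = coded)$contrasts
```
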