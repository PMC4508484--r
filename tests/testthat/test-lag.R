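test_that("same/different recoding follows the category rule", {
  cs <- methods::new("CodedSegments",
    segments = data.frame(dyad_id = "d", interaction_id = 1L, seq_index = 1L,
                          phase = "reference", seg_index = 0:3,
                          t_mid_ms = 25 + 50 * (0:3),
                          i_cat = c(3L, 1L, 2L, NA),
                          w_cat = c(3L, 2L, NA, 2L),
                          stringsAsFactors = FALSE),
    set = "gaze8", segmentMs = 50)
  rc <- recodeSameDifferent(cs)
  s <- segments(rc)
  expect_equal(rc@set, "same6")
  # (I.Target, W.Target) -> Same; (I.Ref, W.Other) -> Different;
  # either uncoded -> neither
  expect_equal(s$w_cat, c(1L, 2L, NA, NA))
  expect_equal(s$i_cat, c(3L, 1L, 2L, NA))   # instructor passes through
})

test_that("alignment curves match a hand-worked example", {
  # instructor A A B B, worker C A A B at 50 ms steps (A = referent,
  # B = bread, C = partner): alignment(+50) = 1, alignment(0) = 0.5
  co <- tinyCorpus(
    bounds = c(0, 40, 80, 120, 160, 200),
    ifix = tiling(c("ing_01", "ing_01", "target_bread", "target_bread")),
    wfix = tiling(c("partner", "ing_01", "ing_01", "target_bread")))
  cv <- curves(alignmentCurves(discretize(co), -100, 100))
  pooled <- function(lag) {
    sub <- cv[cv$lag_ms == lag & cv$n > 0, ]
    sum(sub$alignment * sub$n) / sum(sub$n)
  }
  expect_equal(pooled(50), 1)
  expect_equal(pooled(0), 0.5)
  # denominators: at lag 50 the first segment has no partner
  expect_equal(sum(cv$n[cv$lag_ms == 50]), 3)
  expect_equal(sum(cv$n[cv$lag_ms == 0]), 4)
})

test_that("identical streams peak at zero lag with alignment 1", {
  aois <- rep(c("ing_01", "ing_02", "target_bread"), 20)[1:50]
  co <- tinyCorpus(ifix = tiling(aois), wfix = tiling(aois))
  cv <- alignmentCurves(discretize(co), -500, 500)
  ol <- suppressWarnings(optimalLag(cv, minDenom = 1))
  expect_true(all(ol$lag_ms == 0))
  expect_true(all(ol$alignment == 1))
})

test_that("the curve is invariant under a common time translation", {
  aois <- c("ing_01", "ing_02", "ing_01", "target_bread", "partner",
            "ing_02", "ing_01", "target_bread", "ing_02", "ing_01")
  w <- rev(aois)
  co1 <- tinyCorpus(bounds = c(0, 100, 200, 300, 400, 500),
                    ifix = tiling(aois), wfix = tiling(w))
  co2 <- tinyCorpus(bounds = c(0, 100, 200, 300, 400, 500) + 730,
                    ifix = tiling(aois, from = 730),
                    wfix = tiling(w, from = 730))
  cv1 <- curves(alignmentCurves(discretize(co1), -200, 200))
  cv2 <- curves(alignmentCurves(discretize(co2), -200, 200))
  expect_equal(cv1, cv2)
})

test_that("optimal-lag ties break toward small then positive lags", {
  mk <- function(align, lags, n = 100) {
    methods::new("AlignmentCurveSet",
                 curves = data.frame(phase = "action", lag_ms = lags,
                                     alignment = align, n = n),
                 segmentMs = 50)
  }
  # unique peak
  ol <- optimalLag(mk(c(0.2, 0.5, 0.3), c(-300, -100, 0)), minDenom = 1)
  expect_equal(ol$lag_ms, -100)
  # tie at -50 / +50 -> +50 with a warning
  expect_warning(
    ol <- optimalLag(mk(c(0.5, 0.2, 0.5), c(-50, 0, 50)), minDenom = 1),
    "tied")
  expect_equal(ol$lag_ms, 50)
  expect_true(ol$tied)
  # flat curve -> 0 with a warning
  expect_warning(
    ol <- optimalLag(mk(rep(0.3, 5), c(-100, -50, 0, 50, 100)),
                     minDenom = 1),
    "flat")
  expect_equal(ol$lag_ms, 0)
})

test_that("alignment equals a brute-force cross-recurrence count", {
  corpus <- generateCorpus(defaultGeneratorConfig(), nDyads = 2,
                           nSequences = 5, seed = 19)
  coded <- discretize(corpus)
  cv <- curves(alignmentCurves(coded, -400, 400, 100))
  s <- segments(coded)
  s <- s[order(s$dyad_id, s$interaction_id, s$seq_index, s$seg_index), ]
  key <- paste(s$dyad_id, s$interaction_id, s$seq_index)
  for (lag in c(-400, -100, 0, 200)) {
    k <- lag / 50
    for (p in c("pre_reference", "action")) {
      num <- den <- 0
      for (t in which(s$phase == p)) {
        src <- t - k
        if (src < 1 || src > nrow(s) || key[src] != key[t]) next
        den <- den + 1
        if (!is.na(s$w_cat[t]) && !is.na(s$i_cat[src]) &&
            s$w_cat[t] == s$i_cat[src]) num <- num + 1
      }
      row <- cv[cv$phase == p & cv$lag_ms == lag, ]
      expect_equal(row$n, den)
      expect_equal(row$alignment, if (den) num / den else NA_real_)
    }
  }
})

test_that("worker-stream shifting matches the curve convention", {
  # shifting by the optimal lag moves the matching worker codes to zero lag
  co <- tinyCorpus(
    bounds = c(0, 40, 80, 120, 160, 200),
    ifix = tiling(c("ing_01", "ing_01", "target_bread", "target_bread")),
    wfix = tiling(c("partner", "ing_01", "ing_01", "target_bread")))
  coded <- discretize(co)
  lags <- stats::setNames(rep(50, 5), gazePhases())
  sh <- shiftWorker(coded, lags)
  s <- segments(sh)
  # new worker code at t is the original at t + 50ms; the last segment has
  # no partner and becomes uncoded
  expect_equal(s$w_cat, c(1L, 1L, 3L, NA))
  # zero lags leave the stream unchanged
  s0 <- segments(shiftWorker(coded, lags * 0))
  expect_equal(s0$w_cat, segments(coded)$w_cat)
})

test_that("the shifted space orders phases by coupling strength", {
  # phase-varying coupling with everything else phase-constant: after
  # recoding, stronger-coupled phases carry more W.Same mass
  cfg <- flatConfig(rho = 0.3, leadMs = 0)
  cfg <- modifyConfig(cfg, rho = c(0.05, 0.22, 0.4, 0.58, 0.75))
  corpus <- generateCorpus(cfg, nDyads = 5, nSequences = 12, seed = 23)
  coded <- discretize(corpus)
  sh <- shiftedENA(coded, stats::setNames(rep(0, 5), gazePhases()))
  sums <- meanNetwork(sh$space, sh$units, by = "phase")
  sameIdx <- grep("W.Same", codePairs("same6"), fixed = TRUE)
  sameMass <- sapply(gazePhases(), function(p)
    sum(sums[[p]]$meanNetwork[sameIdx]))
  expect_true(all(diff(sameMass) > 0))
})

test_that("single-unit corpora cannot span a space", {
  co <- tinyCorpus(ifix = tiling(rep("ing_01", 10)),
                   wfix = tiling(rep("ing_01", 10)))
  coded <- discretize(co)
  expect_error(
    shiftedENA(coded, stats::setNames(rep(0, 5), gazePhases())),
    "degenerate|at least 2")
})
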