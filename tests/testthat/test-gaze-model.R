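test_that("fixation IO validates and round-trips", {
  tmp <- withr::local_tempdir()
  fp <- file.path(tmp, "fix.tsv")

  # empty file with header -> empty collection
  writeLines("dyad_id\tinteraction_id\trole\tt_start_ms\tt_end_ms\taoi_raw",
             fp)
  expect_equal(nrow(readFixations(fp)), 0)

  # overlapping intervals within one worker -> error naming rows
  bad <- rbind(fixRow(role = "worker", start = 0, end = 200, aoi = "ing_01"),
               fixRow(role = "worker", start = 150, end = 300,
                      aoi = "ing_02"))
  .writeTab <- function(x, p) utils::write.table(x, p, sep = "\t",
                                                 row.names = FALSE,
                                                 quote = FALSE)
  .writeTab(bad, fp)
  expect_error(readFixations(fp), "overlapping")

  # unknown role -> error
  ugly <- fixRow(role = "observer", start = 0, end = 100, aoi = "ing_01")
  .writeTab(ugly, fp)
  expect_error(readFixations(fp), "role")

  # well-formed rows come back sorted by onset
  good <- rbind(fixRow(role = "worker", start = 500, end = 700,
                       aoi = "ing_01"),
                fixRow(role = "worker", start = 0, end = 200,
                       aoi = "partner"),
                fixRow(role = "instructor", start = 100, end = 400,
                       aoi = "target_bread"),
                fixRow(role = "worker", start = 200, end = 450,
                       aoi = "unmapped"))
  .writeTab(good, fp)
  fx <- readFixations(fp)
  expect_equal(nrow(fx), 4)
  expect_true(!is.unsorted(fx$t_start_ms[fx$role == "worker"]))

  # full corpus write/read round-trip is identity
  corpus <- generateCorpus(defaultGeneratorConfig(), nDyads = 2,
                           nSequences = 3, seed = 11)
  sp <- file.path(tmp, "seq.tsv")
  writeGazeCorpus(corpus, fp, sp)
  back <- readGazeCorpus(fp, sp)
  expect_equal(fixations(back), fixations(corpus))
  expect_equal(sequences(back), sequences(corpus))
})

test_that("raw AOI labels map to role-relative codes", {
  expect_equal(mapGazeCode("ing_03", "instructor", "ing_03"),
               "I.Gaze_Reference")
  expect_equal(mapGazeCode("target_bread", "worker", "ing_03"),
               "W.Gaze_Target")
  expect_equal(mapGazeCode("partner", "worker", "ing_03"), "W.Gaze_Person")
  expect_equal(mapGazeCode("ing_09", "worker", "ing_03"), "W.Gaze_Other")
  expect_true(is.na(mapGazeCode("unmapped", "instructor", "ing_03")))
  # sequence-relative: same AOI flips between Reference and Other
  expect_equal(mapGazeCode("ing_03", "worker", "ing_07"), "W.Gaze_Other")
})

test_that("discretize codes segment midpoints on the sequence grid", {
  # one 100 ms instructor fixation on the referent -> 2 segments, only
  # I.Gaze_Reference active
  co <- tinyCorpus(ifix = data.frame(start = 0, end = 100, aoi = "ing_01"))
  cs <- discretize(co)
  s <- segments(cs)
  expect_equal(sum(s$i_cat == 1L, na.rm = TRUE), 2)
  expect_true(all(is.na(s$w_cat)))

  # both participants on the bread for 150 ms -> 3 segments both Target
  co <- tinyCorpus(ifix = data.frame(start = 0, end = 150,
                                     aoi = "target_bread"),
                   wfix = data.frame(start = 0, end = 150,
                                     aoi = "target_bread"))
  s <- segments(discretize(co))
  both <- !is.na(s$i_cat) & !is.na(s$w_cat)
  expect_equal(sum(both & s$i_cat == 3L & s$w_cat == 3L), 3)

  # half-open intervals: a fixation ending exactly at a segment midpoint
  # does not cover it
  co <- tinyCorpus(ifix = data.frame(start = 0, end = 25, aoi = "ing_01"))
  s <- segments(discretize(co))
  expect_true(all(is.na(s$i_cat)))

  # segment grid is anchored at the sequence start and tiles phases
  co <- tinyCorpus(bounds = c(120, 620, 1120, 1620, 2120, 2620),
                   ifix = data.frame(start = 120, end = 2620,
                                     aoi = "ing_01"))
  s <- segments(discretize(co))
  expect_equal(s$t_mid_ms[1], 145)
  expect_equal(nrow(s), 50)
  # segment count per phase = floor(duration / 50) here (500 ms phases)
  expect_equal(unname(table(s$phase)[gazePhases()]),
               rep(10L, 5), ignore_attr = TRUE)
})

test_that("segment counts per phase stay within one of duration/segment", {
  corpus <- generateCorpus(defaultGeneratorConfig(), nDyads = 2,
                           nSequences = 5, seed = 3)
  s <- segments(discretize(corpus))
  sq <- sequences(corpus)
  for (i in seq_len(nrow(sq))) {
    for (p in gazePhases()) {
      dur <- sq[[paste0(p, "_end_ms")]][i] - sq[[paste0(p, "_start_ms")]][i]
      got <- sum(s$phase == p & s$seq_index == sq$seq_index[i] &
                   s$dyad_id == sq$dyad_id[i] &
                   s$interaction_id == sq$interaction_id[i])
      expect_lte(abs(got - floor(dur / 50)), 1)
    }
  }
  # at most one active code per participant is structural in the integer
  # representation; check the expanded indicator obeys it too
  m <- segmentMatrix(discretize(corpus))
  expect_true(all(rowSums(m[, 1:4]) <= 1))
  expect_true(all(rowSums(m[, 5:8]) <= 1))
})

test_that("descriptive statistics match their definitions and an oracle", {
  # identical streams that never visit the partner: mutual 0%, shared 100%
  aois <- rep(c("ing_01", "ing_02", "target_bread", "unmapped"), 13)[1:50]
  co <- tinyCorpus(ifix = tiling(aois), wfix = tiling(aois))
  ds <- descriptiveStats(co)
  expect_equal(ds$mutual_gaze_pct, 0)
  expect_equal(ds$same_target_pct, 100)

  # worker first fixates the referent exactly 1000 ms after onset
  co <- tinyCorpus(
    ifix = data.frame(start = 0, end = 2500, aoi = "ing_02"),
    wfix = data.frame(start = c(0, 1500), end = c(1500, 2500),
                      aoi = c("ing_02", "ing_01")))
  ds <- descriptiveStats(co)
  expect_equal(ds$worker_latency_s, 1.0)

  # corpus without reference-onset annotations -> latencies undefined
  sq <- sequences(co)
  sq$reference_onset_ms <- NA_integer_
  ds2 <- descriptiveStats(GazeCorpus(fixations(co), sq))
  expect_true(is.na(ds2$worker_latency_s))
  expect_true(is.na(ds2$instructor_lead_s))

  # oracle equivalence: brute-force midpoint scan over fixations
  corpus <- generateCorpus(defaultGeneratorConfig(), nDyads = 2,
                           nSequences = 4, seed = 9)
  ds <- descriptiveStats(corpus)
  fx <- fixations(corpus)
  sq <- sequences(corpus)
  nBoth <- nSame <- nMutual <- 0
  for (i in seq_len(nrow(sq))) {
    s0 <- sq$pre_reference_start_ms[i]; s5 <- sq$post_action_end_ms[i]
    mids <- seq(s0 + 25, s5 - 1, by = 50)
    mids <- mids[mids < s0 + 50 * floor((s5 - s0) / 50)]
    codeAt <- function(role, t) {
      f <- fx[fx$dyad_id == sq$dyad_id[i] &
                fx$interaction_id == sq$interaction_id[i] &
                fx$role == role, ]
      hit <- f$t_start_ms <= t & t < f$t_end_ms
      if (!any(hit)) return(NA)
      aoi <- f$aoi_raw[hit][1]
      if (aoi == "unmapped") NA
      else if (aoi == sq$referent_id[i]) "Reference"
      else if (aoi == "target_bread") "Target"
      else if (aoi == "partner") "Person"
      else "Other"
    }
    for (t in mids) {
      a <- codeAt("instructor", t); b <- codeAt("worker", t)
      if (!is.na(a) && !is.na(b)) {
        nBoth <- nBoth + 1
        if (a == b) nSame <- nSame + 1
        if (a == "Person" && b == "Person") nMutual <- nMutual + 1
      }
    }
  }
  expect_equal(ds$same_target_pct, 100 * nSame / nBoth, tolerance = 1e-12)
  expect_equal(ds$mutual_gaze_pct, 100 * nMutual / nBoth, tolerance = 1e-12)
})

test_that("corpus validity catches malformed sequences", {
  sq <- seqRow(bounds = c(0, 500, 1000, 1500, 2000, 2500))
  sq$reference_start_ms <- 600   # break contiguity
  sq$pre_reference_end_ms <- 550
  expect_error(GazeCorpus(fixRow(role = "worker", start = 0, end = 100,
                                 aoi = "ing_01"), sq), "contiguous")
})
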