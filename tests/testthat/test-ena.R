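# Segment table on the gaze8 set built directly from integer codes.
segObj <- function(icat, wcat, unit = "u1") {
  n <- length(icat)
  methods::new("CodedSegments",
    segments = data.frame(dyad_id = unit, interaction_id = 1L,
                          seq_index = 1L, phase = "action",
                          seg_index = seq_len(n) - 1L,
                          t_mid_ms = 25 + 50 * (seq_len(n) - 1),
                          i_cat = as.integer(icat), w_cat = as.integer(wcat),
                          stringsAsFactors = FALSE),
    set = "gaze8", segmentMs = 50)
}

test_that("accumulate counts cross-person co-occurrences", {
  # (I.Ref, W.Ref) x2, (I.Other, W.Target) x1
  cs <- segObj(c(1, 1, 2), c(1, 1, 3))
  u <- accumulateUnits(cs, by = "dyad_id")
  U <- adjacencyCounts(u)[1, ]
  expect_equal(unname(U["I.Gaze_Reference & W.Gaze_Reference"]), 2)
  expect_equal(unname(U["I.Gaze_Other & W.Gaze_Target"]), 1)
  expect_equal(sum(U), 3)

  # a segment with only an instructor code contributes nothing
  u2 <- accumulateUnits(segObj(c(1, 2), c(1, NA)), by = "dyad_id")
  expect_equal(sum(adjacencyCounts(u2)), 1)

  # empty unit is flagged
  u3 <- accumulateUnits(segObj(c(1, NA), c(NA, 2)), by = "dyad_id")
  expect_true(unitKeys(u3)$empty)
})

test_that("accumulate equals a brute-force double loop", {
  set.seed(42)
  n <- 10000
  icat <- sample(c(1:4, NA), n, replace = TRUE)
  wcat <- sample(c(1:4, NA), n, replace = TRUE)
  unit <- sample(c("a", "b", "c"), n, replace = TRUE)
  u <- accumulateUnits(segObj(icat, wcat, unit), by = "dyad_id")
  pairs <- codePairs("gaze8")
  for (g in c("a", "b", "c")) {
    brute <- stats::setNames(numeric(16), pairs)
    for (i in which(unit == g)) {
      if (is.na(icat[i]) || is.na(wcat[i])) next
      pr <- paste0("I.Gaze_", gazeCategories()[icat[i]], " & W.Gaze_",
                   gazeCategories()[wcat[i]])
      brute[pr] <- brute[pr] + 1
    }
    row <- which(unitKeys(u)$dyad_id == g)
    expect_equal(adjacencyCounts(u)[row, ], brute, ignore_attr = FALSE)
  }
})

test_that("normalisation projects onto the unit hypersphere", {
  expect_equal(normalizeAdjacency(c(2, 1, 0)), c(0.8944272, 0.4472136, 0),
               tolerance = 1e-6)
  v <- c(3, 0, 4, 1)
  expect_equal(normalizeAdjacency(7 * v), normalizeAdjacency(v))
  set.seed(1)
  for (i in 1:20) {
    u <- runif(16)
    expect_equal(sqrt(sum(normalizeAdjacency(u)^2)), 1, tolerance = 1e-9)
  }
  expect_error(normalizeAdjacency(rep(0, 16)), "empty unit")
})

# Random non-empty unit set for space tests.
randomUnits <- function(nUnits = 12, seed = 7) {
  set.seed(seed)
  U <- matrix(rpois(nUnits * 16, 8), nUnits, 16,
              dimnames = list(NULL, codePairs("gaze8")))
  methods::new("ENAUnitSet",
               units = data.frame(unit = paste0("u", seq_len(nUnits)),
                                  empty = FALSE),
               U = U, nU = U / sqrt(rowSums(U^2)), set = "gaze8")
}

test_that("the SVD space has the promised structure", {
  us <- randomUnits()
  sp <- buildSpace(us)
  V <- loadings(sp)
  expect_equal(unname(crossprod(V)), diag(2), tolerance = 1e-9)
  expect_gte(sp@varianceExplained[1], sp@varianceExplained[2])
  # training projections have zero mean and are reproduced by projectUnits
  expect_equal(colMeans(projections(sp)), c(SVD1 = 0, SVD2 = 0),
               tolerance = 1e-12)
  expect_equal(projectUnits(sp, us), projections(sp), ignore_attr = TRUE)
  # deterministic sign convention: largest-magnitude entry positive
  for (j in 1:2) expect_gt(V[which.max(abs(V[, j])), j], 0)

  # order invariance up to re-indexing
  perm <- sample(nrow(us@U))
  us2 <- methods::new("ENAUnitSet", units = us@units[perm, , drop = FALSE],
                      U = us@U[perm, ], nU = us@nU[perm, ], set = "gaze8")
  sp2 <- buildSpace(us2)
  expect_equal(loadings(sp2), loadings(sp), tolerance = 1e-9)
  expect_equal(projections(sp2)[order(perm), ], projections(sp),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("collinear units put all variance on dimension 1", {
  # two distinct unit vectors (plus a repeat): the centered cloud spans a
  # line, so the first dimension carries all the variance and the kept
  # rank collapses to 1
  U <- matrix(0, 3, 16, dimnames = list(NULL, codePairs("gaze8")))
  U[1, 1:2] <- c(2, 1); U[2, 1:2] <- c(1, 2); U[3, 1:2] <- c(2, 1)
  us <- methods::new("ENAUnitSet",
                     units = data.frame(unit = paste0("u", 1:3),
                                        empty = FALSE),
                     U = U, nU = U / sqrt(rowSums(U^2)), set = "gaze8")
  sp <- buildSpace(us, position = FALSE)
  expect_gt(sp@varianceExplained[1], 0.999)
  expect_equal(ncol(loadings(sp)), 1)
})

test_that("degenerate spaces are rejected", {
  U <- matrix(rep(c(2, 1, rep(0, 14)), each = 4), 4, 16,
              dimnames = list(NULL, codePairs("gaze8")))
  us <- methods::new("ENAUnitSet",
                     units = data.frame(unit = letters[1:4], empty = FALSE),
                     U = U, nU = U / sqrt(rowSums(U^2)), set = "gaze8")
  expect_error(buildSpace(us), "degenerate")
})

test_that("projections reconstruct centered vectors up to truncation", {
  us <- randomUnits(10, seed = 3)
  sp <- buildSpace(us, d = 2, position = FALSE)
  Xc <- sweep(us@nU, 2, centerVector(sp))
  full <- svd(Xc)
  k <- 2
  trunc <- full$u[, 1:k] %*% diag(full$d[1:k]) %*% t(full$v[, 1:k])
  recon <- projections(sp) %*% t(loadings(sp))
  expect_equal(recon, trunc, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("node positioning solves the centroid least squares", {
  # two units with disjoint single active pairs: the optimum puts each
  # unit's edge midpoint exactly on its projection (zero residual)
  U <- matrix(0, 2, 16, dimnames = list(NULL, codePairs("gaze8")))
  U[1, "I.Gaze_Reference & W.Gaze_Reference"] <- 5
  U[2, "I.Gaze_Target & W.Gaze_Target"] <- 3
  us <- methods::new("ENAUnitSet",
                     units = data.frame(unit = c("a", "b"), empty = FALSE),
                     U = U, nU = U / sqrt(rowSums(U^2)), set = "gaze8")
  sp <- buildSpace(us, d = 1)
  expect_equal(sp@positioningResidual, 0, tolerance = 1e-12)
  nd <- nodePositions(sp)
  P <- projections(sp)
  expect_equal((nd["I.Gaze_Reference", ] + nd["W.Gaze_Reference", ]) / 2,
               P[1, 1], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal((nd["I.Gaze_Target", ] + nd["W.Gaze_Target", ]) / 2,
               P[2, 1], tolerance = 1e-9, ignore_attr = TRUE)
  # codes never observed in a co-occurrence are unconstrained at the origin
  expect_false(sp@nodeConstrained[["I.Gaze_Person"]])
  expect_equal(unname(nd["I.Gaze_Person", ]), 0)
})

test_that("positioning beats random layouts and is translation-equivariant", {
  us <- randomUnits(14, seed = 5)
  sp <- buildSpace(us)
  M <- dyadENA:::.centroidDesign(us@nU, "gaze8")
  P <- projections(sp)
  obj <- function(X) sum((P - M %*% X)^2)
  expect_equal(sp@positioningResidual, obj(nodePositions(sp)),
               tolerance = 1e-9)
  set.seed(99)
  rand <- replicate(1000, obj(matrix(rnorm(16, sd = 0.5), 8, 2)))
  expect_true(all(sp@positioningResidual <= rand + 1e-12))

  # translating every projection translates every node by the same vector
  shift <- c(0.3, -0.2)
  sp2 <- sp
  sp2@projections <- sweep(P, 2, shift, "+")
  sp2 <- positionNodes(sp2, us)
  expect_equal(nodePositions(sp2),
               sweep(nodePositions(sp), 2, shift, "+"), tolerance = 1e-8)
})

test_that("mean networks and centroids summarise groups exactly", {
  us <- randomUnits(12, seed = 8)
  sp <- buildSpace(us)
  # identical units: mean equals the member, zero CI width
  one <- us@nU[1, ]
  Uid <- matrix(rep(us@U[1, ], each = 5), 5, dimnames = list(NULL, colnames(us@U)))
  usid <- methods::new("ENAUnitSet",
                       units = data.frame(unit = letters[1:5], empty = FALSE),
                       U = Uid, nU = Uid / sqrt(rowSums(Uid^2)), set = "gaze8")
  g <- meanNetwork(sp, usid)
  expect_equal(g$meanNetwork, one, tolerance = 1e-12)
  expect_equal(unname(g$ciHalfWidth), c(0, 0), tolerance = 1e-12)

  # two units: centroid is the midpoint
  g2 <- meanNetwork(sp, us, which = 1:2)
  expect_equal(g2$centroid, colMeans(projections(sp)[1:2, ]),
               tolerance = 1e-12)

  # linearity: part means recombine (weighted by sizes) to the group mean
  gAll <- meanNetwork(sp, us)
  gA <- meanNetwork(sp, us, which = 1:5)
  gB <- meanNetwork(sp, us, which = 6:12)
  expect_equal((5 * gA$meanNetwork + 7 * gB$meanNetwork) / 12,
               gAll$meanNetwork, tolerance = 1e-12)

  # n = 1 group: CI undefined
  g1 <- meanNetwork(sp, us, which = 3)
  expect_true(all(is.na(g1$ciHalfWidth)))
})

test_that("group comparison handles identical and separated groups", {
  us <- randomUnits(12, seed = 13)
  sp <- buildSpace(us)
  cg <- compareGroups(sp, us, 1:6, 1:6, dimension = 1)
  expect_equal(cg$t, 0)
  expect_equal(cg$p, 1)
  expect_equal(cg$d, 0)

  # Cohen's d follows its pooled-SD definition on arbitrary groups
  cg2 <- compareGroups(sp, us, 1:6, 7:12, dimension = 2)
  P <- projectUnits(sp, us)[, 2]
  a <- P[1:6]; b <- P[7:12]
  dref <- (mean(a) - mean(b)) / sqrt((5 * var(a) + 5 * var(b)) / 10)
  expect_equal(cg2$d, dref, tolerance = 1e-12)
  expect_equal(cg2$t, unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-12)

  # no variance in either group with equal means -> t = 0, p = 1
  U1 <- matrix(rep(c(3, 1, rep(0, 14)), each = 4), 4, 16,
               dimnames = list(NULL, codePairs("gaze8")))
  U2 <- matrix(rep(c(0, 0, 5, 2, rep(0, 12)), each = 4), 4, 16,
               dimnames = list(NULL, codePairs("gaze8")))
  Ud <- rbind(U1, U2)
  usd <- methods::new("ENAUnitSet",
                      units = data.frame(unit = letters[1:8], empty = FALSE),
                      U = Ud, nU = Ud / sqrt(rowSums(Ud^2)), set = "gaze8")
  spd <- buildSpace(usd)
  same <- compareGroups(spd, usd, 1:2, 3:4, dimension = 1)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})
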