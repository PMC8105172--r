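test_that("confusion counts cells and masked residues correctly", {
  cm <- confusion(list(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)),
                  list(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)))
  expect_equal(unname(confusionCounts(cm)), c(4, 0, 0, 6, 0))
  cm2 <- confusion(list(c(1L, 1L, NA, 0L)), list(c(1L, 0L, 1L, 1L)))
  expect_equal(unname(confusionCounts(cm2)), c(1, 1, 1, 0, 1))
  expect_error(confusion(list(c(1L, 0L)), list(c(1L, 0L, 1L))),
               "length mismatch")
})

test_that("confusion agrees with a position-by-position brute-force count", {
  set.seed(13)
  lab <- sample(c(0L, 1L, NA), 1e4, replace = TRUE, prob = c(.45, .45, .1))
  st <- sample(c(0L, 1L), 1e4, replace = TRUE)
  cm <- confusionCounts(confusion(list(lab), list(st)))
  brute <- c(0, 0, 0, 0, 0)
  for (i in seq_along(lab)) {
    if (is.na(lab[i])) brute[5] <- brute[5] + 1
    else if (lab[i] == 1 && st[i] == 1) brute[1] <- brute[1] + 1
    else if (lab[i] == 0 && st[i] == 1) brute[2] <- brute[2] + 1
    else if (lab[i] == 1 && st[i] == 0) brute[3] <- brute[3] + 1
    else brute[4] <- brute[4] + 1
  }
  expect_equal(unname(cm), brute)
})

test_that("point metrics reproduce published worked examples", {
  m <- pointMetrics(c(tp = 26, fp = 16, fn = 19, tn = 585))
  expect_equal(roundHalfUp(m[["mcc"]]), 0.569)
  expect_equal(roundHalfUp(m[["f1"]]), 0.598)
  expect_equal(roundHalfUp(m[["bac"]]), 0.776)
  m2 <- pointMetrics(c(tp = 0, fp = 0, fn = 45, tn = 601))
  expect_equal(m2[["mcc"]], 0)
  expect_equal(m2[["f1"]], 0)
  expect_equal(m2[["tnr"]], 1)
  expect_equal(m2[["bac"]], 0.5)
  expect_setequal(attr(m2, "conventions") %in%
                    c("mcc", "f1", "f0.5", "f2", "tpr", "ppv"),
                  TRUE)
  m3 <- pointMetrics(c(tp = 4, fp = 0, fn = 41, tn = 601))
  expect_equal(roundHalfUp(m3[["f1"]]), 0.163)
  expect_equal(m3[["ppv"]], 1)
  expect_equal(roundHalfUp(m3[["tpr"]]), 0.089)
})

test_that("a perfect predictor attains F_max = 1 and AUC = 1", {
  set.seed(3)
  lab <- sample(c(0L, 1L), 500, replace = TRUE)
  ws <- wrapSets(lab, as.numeric(lab), nTargets = 5L)
  cs <- computeCurves(ws$ref, ws$pset, "dataset")
  expect_equal(fMax(cs), 1)
  expect_equal(aucValue(cs), 1)
  expect_true(fMaxThreshold(cs) <= 1)
})

test_that("grid-scan F_max equals the brute-force distinct-threshold maximum", {
  set.seed(29)
  for (i in 1:30) {
    n <- sample(50:1000, 1)
    rs <- randomLabelledScores(n, nLevels = sample(c(5L, 20L, 100L), 1),
                               maskFrac = sample(c(0, 0.1), 1))
    ws <- wrapSets(rs$labels, rs$scores)
    cs <- computeCurves(ws$ref, ws$pset, "dataset")
    expect_identical(fMax(cs), bruteForceFmax(rs$labels, rs$scores))
  }
})

test_that("trapezoidal grid AUC equals the rank-statistic AUC", {
  set.seed(31)
  for (i in 1:10) {
    rs <- randomLabelledScores(sample(100:800, 1), nLevels = 30L)
    ws <- wrapSets(rs$labels, rs$scores)
    cs <- computeCurves(ws$ref, ws$pset, "dataset")
    expect_equal(aucValue(cs), rankAuc(rs$labels, rs$scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under an order-preserving score transform", {
  set.seed(37)
  lab <- sample(c(0L, 1L), 2000, replace = TRUE)
  sc <- roundHalfUp(runif(2000, 0, 0.5))
  ws <- wrapSets(lab, sc)
  cs <- computeCurves(ws$ref, ws$pset, "dataset")
  # doubling is strictly monotone and injective on the rounded half-grid
  ws2 <- wrapSets(lab, roundHalfUp(2 * sc))
  cs2 <- computeCurves(ws2$ref, ws2$pset, "dataset")
  expect_equal(aucValue(cs2), aucValue(cs), tolerance = 1e-12)
})

test_that("uniform random scores give AUC near one half", {
  set.seed(43)
  n <- 1e5
  lab <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.7, 0.3))
  sc <- roundHalfUp(runif(n))
  ws <- wrapSets(lab, sc, nTargets = 50L)
  expect_lt(abs(aucValue(computeCurves(ws$ref, ws$pset, "dataset")) - 0.5),
            0.01)
})

test_that("dataset-strategy confusion equals the sum of per-target matrices", {
  set.seed(47)
  rs <- randomLabelledScores(3000, maskFrac = 0.15)
  ws <- wrapSets(rs$labels, rs$scores, nTargets = 17L)
  per <- confusion(ws$ref, ws$pset, perTarget = TRUE)
  total <- Reduce(addConfusion, per)
  expect_equal(confusionCounts(total),
               confusionCounts(confusion(ws$ref, ws$pset)))
})

test_that("target strategy averages per-target metrics (naive recompute)", {
  set.seed(53)
  rs <- randomLabelledScores(600, nLevels = 10L)
  ws <- wrapSets(rs$labels, rs$scores, nTargets = 6L)
  ct <- computeCurves(ws$ref, ws$pset, "target")
  labs <- as.list(referenceLabels(ws$ref))
  scos <- as.list(predictionScores(ws$pset))
  naiveF1 <- sapply(thresholdGrid(), function(thr) {
    mean(mapply(function(l, s) {
      pred <- s >= thr - 1e-9
      tp <- sum(l == 1L & pred, na.rm = TRUE)
      fp <- sum(l == 0L & pred, na.rm = TRUE)
      fn <- sum(l == 1L & !pred, na.rm = TRUE)
      if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    }, labs, scos))
  })
  expect_equal(curveTable(ct)$f1, naiveF1, tolerance = 1e-12)
  expect_equal(fMax(ct), max(naiveF1), tolerance = 1e-12)
})

test_that("masked positions never influence any metric", {
  set.seed(59)
  lab <- sample(c(0L, 1L, NA), 4000, replace = TRUE, prob = c(.4, .3, .3))
  sc <- roundHalfUp(runif(4000))
  ws <- wrapSets(lab, sc, nTargets = 8L)
  base <- computeCurves(ws$ref, ws$pset, "dataset")
  sc2 <- sc
  sc2[is.na(lab)] <- roundHalfUp(runif(sum(is.na(lab))))
  ws2 <- wrapSets(lab, sc2, nTargets = 8L)
  pert <- computeCurves(ws2$ref, ws2$pset, "dataset")
  expect_identical(curveTable(pert), curveTable(base))
  expect_identical(confusionCounts(confusion(ws2$ref, ws2$pset)),
                   confusionCounts(confusion(ws$ref, ws$pset)))
})

test_that("F_max dominates F1 at the resolved default threshold", {
  set.seed(61)
  for (i in 1:10) {
    rs <- randomLabelledScores(sample(200:800, 1))
    ws <- wrapSets(rs$labels, rs$scores)
    cs <- computeCurves(ws$ref, ws$pset, "dataset")
    f1 <- pointMetrics(confusion(ws$ref, ws$pset))[["f1"]]
    expect_gte(fMax(cs), f1 - 1e-12)
  }
})

test_that("bootstrap is seed-reproducible and degenerates to zero width", {
  set.seed(67)
  lab <- sample(c(0L, 1L), 800, replace = TRUE)
  ws <- wrapSets(lab, as.numeric(lab), nTargets = 4L)
  b1 <- bootstrapMetric(ws$ref, ws$pset, "f1", nReplicates = 200, seed = 9)
  b2 <- bootstrapMetric(ws$ref, ws$pset, "f1", nReplicates = 200, seed = 9)
  expect_identical(replicateValues(b1), replicateValues(b2))
  expect_identical(confInt(b1), confInt(b2))
  # perfect constant predictor: every replicate is 1, CI width 0
  expect_true(all(replicateValues(b1) == 1))
  expect_equal(unname(diff(confInt(b1))), 0)

  rs <- randomLabelledScores(600)
  ws2 <- wrapSets(rs$labels, rs$scores)
  b3 <- bootstrapMetric(ws2$ref, ws2$pset, "f1", nReplicates = 200,
                        seed = 10)
  b4 <- bootstrapMetric(ws2$ref, ws2$pset, "f1", nReplicates = 200,
                        seed = 11)
  expect_false(identical(replicateValues(b3), replicateValues(b4)))
})

test_that("paired method comparison matches a direct t computation", {
  expect_equal(as.numeric(compareMethods(c(1, 2, 3), c(1, 2, 3))), 1)
  set.seed(71)
  x <- 0.5 + rnorm(100, sd = 0.01)
  y <- 0.9 + rnorm(100, sd = 0.01)
  p <- compareMethods(x, y)
  expect_lt(p, 0.001)
  # independent recomputation from the t statistic
  d <- x - y
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(p, 2 * pt(-abs(tstat), length(d) - 1), tolerance = 1e-12)
  # symmetry
  expect_equal(compareMethods(y, x), p, tolerance = 1e-12)
  # zero-variance degenerate case
  pd <- compareMethods(c(1, 1, 1), c(0, 0, 0))
  expect_equal(as.numeric(pd), 0)
  expect_true(isTRUE(attr(pd, "degenerate")))
})
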