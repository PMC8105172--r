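test_that("random baseline is deterministic and splits near one half", {
  tg <- toyTargets(T1 = 4000, T2 = 4000)
  a <- randomBaseline(tg, seed = 5)
  b <- randomBaseline(tg, seed = 5)
  expect_identical(as.list(predictionScores(a)), as.list(predictionScores(b)))
  expect_equal(effectiveThreshold(a), 0.5)
  frac <- mean(unlist(predictionStates(a)) == 1L)
  # binomial bound: 8000 draws, p = 0.5 (scores >= 0.5), ~4 sigma
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 8000))
})

test_that("shuffled baseline preserves the dataset positive count exactly", {
  tg <- toyTargets(T1 = 200, T2 = 50, T3 = 500)
  ann <- toyAnnotations(rbind(annRow("T1", "disorder", 1, 150),
                              annRow("T3", "disorder", 100, 140)), tg)
  ref <- buildReference(tg, ann, "disprot")
  sb <- shuffledBaseline(ref, seed = 8)
  expect_equal(sum(unlist(predictionStates(sb)) == 1L),
               referenceComposition(ref)$positives)
  # heterogeneous prevalence: some per-target count must differ
  perTargetRef <- referenceComposition(ref)$perTarget$positives
  perTargetPred <- vapply(as.list(predictionStates(sb)),
                          function(x) sum(x == 1L), integer(1))
  expect_true(any(perTargetPred != perTargetRef))
})

test_that("shuffled baseline precision and recall approach the prevalence", {
  # closed form: drawing the predicted-positive set as a random permutation
  # of labels makes E[TP] = P * P / n, hence PPV ~ TPR ~ prevalence
  tg <- toyTargets(T1 = 20000)
  ann <- toyAnnotations(annRow("T1", "disorder", 1, 5000), tg)
  ref <- buildReference(tg, ann, "disprot")
  prev <- 5000 / 20000
  sb <- shuffledBaseline(ref, seed = 2)
  m <- pointMetrics(confusion(ref, sb))
  expect_lt(abs(m[["ppv"]] - prev), 0.02)
  expect_lt(abs(m[["tpr"]] - prev), 0.02)
})

test_that("shuffled baseline masks inertly in disprot_pdb mode", {
  tg <- toyTargets(T1 = 100)
  ann <- toyAnnotations(rbind(annRow("T1", "disorder", 1, 30),
                              annRow("T1", "structure_observed", 41, 80)),
                        tg)
  ref <- buildReference(tg, ann, "disprot_pdb")
  sb <- shuffledBaseline(ref, seed = 3)
  cm <- confusionCounts(confusion(ref, sb))
  expect_equal(unname(cm[["tp"]] + cm[["fp"]]), 30)   # permuted pool only
  expect_equal(unname(cm[["masked"]]), 30)   # 100 - 30 disorder - 40 structure
})

test_that("Jensen-Shannon divergence matches hand-evaluated entropies", {
  bg <- blosum62Background()
  expect_equal(jsDivergence(bg, bg), 0)
  # point mass on one residue vs the uniform distribution, by direct
  # evaluation of H((p+q)/2) - (H(p)+H(q))/2 in base 2
  p <- setNames(numeric(20), names(bg)); p["A"] <- 1
  q <- rep(1 / 20, 20)
  m <- (p + q) / 2
  hm <- -sum(m[m > 0] * log2(m[m > 0]))
  hq <- log2(20)
  expect_equal(jsDivergence(p, q), hm - hq / 2, tolerance = 1e-12)
  # bounded in [0,1] over random simplex points
  set.seed(17)
  for (i in 1:200) {
    x <- rexp(20); x <- x / sum(x)
    y <- rexp(20); y <- y / sum(y)
    v <- jsDivergence(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("conservation scores are invariant under joint alphabet permutation", {
  set.seed(19)
  bg <- blosum62Background()
  p <- rexp(20); p <- p / sum(p)
  perm <- sample(20)
  expect_equal(jsDivergence(p, unname(bg)),
               jsDivergence(p[perm], unname(bg)[perm]), tolerance = 1e-12)
})

test_that("conservation baseline scores, classifies with the strict rule, and inverts", {
  bg <- blosum62Background()
  pm <- rbind(bg,                        # background itself -> JSD 0
              c(1, rep(0, 19)),          # point mass -> large JSD
              bg)
  profiles <- list(T1 = pm)
  cb <- conservationBaseline(profiles)
  sc <- predictionScores(cb)[["T1"]]
  expect_equal(sc[1], 0)
  expect_equal(sc[2], roundHalfUp(jsDivergence(c(1, rep(0, 19)),
                                               unname(bg))))
  expect_equal(predictionStates(cb)[["T1"]], as.integer(sc > 0.4))
  inv <- suppressWarnings(conservationBaseline(profiles, invert = TRUE))
  expect_equal(predictionScores(inv)[["T1"]], roundHalfUp(1 - sc))
  # malformed profiles error
  bad <- list(T1 = rbind(bg * 2))
  expect_error(conservationBaseline(bad), "not summing to 1")
})

test_that("structure complement scores the complement and all-1 for uncovered targets", {
  tg <- toyTargets(T1 = 10, T2 = 6)
  cov <- makeAnnotations(annRow("T1", "structure_observed", 3, 7), tg)
  pb <- structureComplementBaseline(cov, tg)
  expect_equal(predictionScores(pb)[["T1"]],
               c(1, 1, 0, 0, 0, 0, 0, 1, 1, 1))
  expect_equal(predictionScores(pb)[["T2"]], rep(1, 6))  # no structure
  # full coverage -> all zero
  cov2 <- makeAnnotations(rbind(annRow("T1", "structure_observed", 1, 10),
                                annRow("T2", "structure_observed", 1, 6)),
                          tg)
  pb2 <- suppressWarnings(structureComplementBaseline(cov2, tg))
  expect_true(all(unlist(predictionScores(pb2)) == 0))
})

test_that("structure complement has zero false positives against its own disprot_pdb reference", {
  set.seed(23)
  d <- generateDataset(fixtureSpec(nTargets = 40, seed = 23))
  ref <- buildReference(d$targets, d$annotations, "disprot_pdb")
  cov <- d$annotations[S4Vectors::mcols(d$annotations)$class ==
                         "structure_observed"]
  pb <- structureComplementBaseline(cov, d$targets)
  cm <- confusionCounts(confusion(ref, pb))
  # negatives are exactly the structure-covered residues, which score 0
  expect_equal(unname(cm[["fp"]]), 0)
})

test_that("baseline outputs round-trip through the prediction format unchanged", {
  tg <- toyTargets(T1 = 25, T2 = 13)
  rb <- randomBaseline(tg, seed = 29)
  path <- withr::local_tempfile(fileext = ".caid")
  writePredictions(rb, path)
  back <- readPredictions(path, "Random")
  expect_identical(as.list(predictionScores(back)),
                   as.list(predictionScores(rb)))
  expect_identical(as.list(predictionStates(back)),
                   as.list(predictionStates(rb)))
})

test_that("profiles round-trip through the profile table format", {
  set.seed(31)
  d <- generateDataset(fixtureSpec(nTargets = 3, seed = 31))
  profiles <- generateProfiles(d, contrast = 0.5)
  dir <- withr::local_tempdir()
  writeProfiles(profiles, dir)
  back <- readProfiles(dir)
  expect_setequal(names(back), names(profiles))
  for (tid in names(profiles))
    expect_equal(back[[tid]], profiles[[tid]], tolerance = 1e-9,
                 ignore_attr = TRUE)
})
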