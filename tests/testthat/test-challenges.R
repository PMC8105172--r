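test_that("IDP challenge counts protein-level calls at the 95% threshold", {
  set.seed(101)
  d <- generateDataset(fixtureSpec(nTargets = 60, idpFraction = 10 / 60,
                                   seed = 101))
  ref <- buildReference(d$targets, d$annotations, "disprot")
  nIdp <- sum(d$truth$perTarget$is_idp)
  expect_equal(nIdp, 10)
  # a perfect residue predictor recovers the annotated IDP set exactly
  perfect <- resolveThreshold(newPredictionSet(
    "Perfect", lapply(as.list(referenceLabels(ref)), as.numeric)))
  res <- idpChallenge(ref, list(perfect))
  expect_equal(res$ranking$tp, nIdp)
  expect_equal(res$ranking$tn, 60 - nIdp)
  expect_equal(res$ranking$f1, 1)
  # saturating predictor: everything called disordered
  allOne <- resolveThreshold(newPredictionSet(
    "AllOne", lapply(as.list(referenceLabels(ref)),
                     function(x) rep(1, length(x)))))
  res2 <- idpChallenge(ref, list(allOne))
  expect_equal(res2$ranking$tpr, 1)
  expect_equal(res2$ranking$tnr, 0)
})

test_that("IDP threshold limits: 0 annotates everything, >1 nothing", {
  set.seed(103)
  d <- generateDataset(fixtureSpec(nTargets = 20, seed = 103))
  ref <- buildReference(d$targets, d$annotations, "disprot")
  pred <- generatePredictions(d, seed = 2)
  r0 <- idpChallenge(ref, list(pred), idpThreshold = 0)
  expect_true(all(r0$calls[[1]]$annotated_idp))
  r2 <- idpChallenge(ref, list(pred), idpThreshold = 1.01)
  expect_false(any(r2$calls[[1]]$annotated_idp))
  expect_false(any(r2$calls[[1]]$predicted_idp))
})

test_that("IDP ranking reproduces a published worked example row", {
  # protein-level confusion with tn=585 fp=16 fn=19 tp=26 -> F1 0.598
  m <- pointMetrics(c(tp = 26, fp = 16, fn = 19, tn = 585))
  expect_equal(roundHalfUp(m[["f1"]]), 0.598)
  tab <- idpBenchmarkTable()
  expect_equal(tab$f1[tab$method == "fIDPnn"], 0.598)
  # table rows are sorted by F1, as the ranking contract requires
  expect_true(all(diff(tab$f1) <= 0))
})

test_that("challenge runs are deterministic and self-describing", {
  set.seed(107)
  d <- generateDataset(fixtureSpec(nTargets = 25, seed = 107))
  ref <- buildReference(d$targets, d$annotations, "disprot")
  preds <- list(generatePredictions(d, noisyPredictorSpec(4, 2, 2, 4),
                                    seed = 5, methodName = "good"),
                generatePredictions(d, noisyPredictorSpec(2.2, 2, 2, 2.2),
                                    seed = 6, methodName = "weak"))
  r1 <- runChallenge(ref, preds, nReplicates = 100, seed = 42)
  r2 <- runChallenge(ref, preds, nReplicates = 100, seed = 42)
  expect_identical(r1$ranking, r2$ranking)
  expect_identical(r1$pvalues, r2$pvalues)
  expect_equal(r1$ranking$method[1], "good")
  expect_true(all(c("reference_mode", "strategy", "threshold") %in%
                    names(r1$ranking)))
  expect_equal(unique(r1$ranking$reference_mode), "disprot")
  # the two methods genuinely differ -> tiny p-value, symmetric matrix
  expect_lt(r1$pvalues["good", "weak"], 0.001)
  expect_equal(r1$pvalues["good", "weak"], r1$pvalues["weak", "good"])
})

test_that("report bundles are written with ranking, curves and p-values", {
  set.seed(109)
  d <- generateDataset(fixtureSpec(nTargets = 10, seed = 109))
  ref <- buildReference(d$targets, d$annotations, "disprot")
  pred <- generatePredictions(d, seed = 7, methodName = "m1")
  rep1 <- runChallenge(ref, list(pred), nReplicates = 50, seed = 1)
  dir <- withr::local_tempdir()
  writeReport(rep1, dir)
  expect_true(file.exists(file.path(dir, "ranking.tsv")))
  expect_true(file.exists(file.path(dir, "ranking.json")))
  expect_true(file.exists(file.path(dir, "curves_m1_dataset.tsv")))
  expect_true(file.exists(file.path(dir, "pvalues.tsv")))
  back <- read.delim(file.path(dir, "ranking.tsv"))
  expect_equal(back$f_max, rep1$ranking$f_max, tolerance = 1e-9)
})

test_that("unreadable prediction files are skipped and listed as exclusions", {
  set.seed(113)
  d <- generateDataset(fixtureSpec(nTargets = 8, seed = 113))
  ref <- buildReference(d$targets, d$annotations, "disprot")
  dir <- withr::local_tempdir()
  writePredictions(generatePredictions(d, seed = 3, methodName = "ok"),
                   file.path(dir, "ok.caid"))
  writeLines(c(">T-unknown", "1\tM\tnot-a-number"), file.path(dir, "bad.caid"))
  expect_message(rep1 <- runChallenge(ref, dir, nReplicates = 50, seed = 1),
                 "skipping unreadable")
  expect_equal(rep1$ranking$method, "ok")
  expect_match(rep1$exclusions, "bad.caid")
})

test_that("subset evaluation restricts consistently and adds up", {
  set.seed(127)
  d <- generateDataset(fixtureSpec(nTargets = 24, seed = 127))
  ref <- buildReference(d$targets, d$annotations, "disprot")
  pred <- generatePredictions(d, seed = 9, methodName = "m")
  full <- runChallenge(ref, list(pred), nReplicates = 50, seed = 3)
  allIds <- names(ref)
  same <- subsetEvaluation(ref, list(pred), allIds, nReplicates = 50,
                           seed = 3)
  expect_equal(same$ranking, full$ranking)
  # disjoint subsets: dataset-strategy confusion matrices sum to the total
  half <- length(allIds) %/% 2
  cmA <- confusion(subsetReference(ref, allIds[1:half]), pred)
  cmB <- confusion(subsetReference(ref, allIds[(half + 1):length(allIds)]),
                   pred)
  cmAll <- confusion(ref, pred)
  expect_equal(confusionCounts(addConfusion(cmA, cmB)),
               confusionCounts(cmAll))
  expect_error(subsetEvaluation(ref, list(pred), character()), "empty")
})

test_that("rank keys equal to three decimals order deterministically by name", {
  set.seed(131)
  d <- generateDataset(fixtureSpec(nTargets = 10, seed = 131))
  ref <- buildReference(d$targets, d$annotations, "disprot")
  base <- generatePredictions(d, seed = 11, methodName = "zeta")
  twin <- base
  twin@methodName <- "alpha"
  rep1 <- runChallenge(ref, list(base, twin), nReplicates = 50, seed = 1)
  expect_equal(rep1$ranking$method, c("alpha", "zeta"))
})
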