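# shared helpers: tiny in-code fixtures for the unit suites

# named length vector -> toy target set
toyTargets <- function(...) {
  lens <- c(...)
  stopifnot(!is.null(names(lens)))
  lens
}

toyAnnotations <- function(df, targets) makeAnnotations(df, targets)

annRow <- function(target_id, class, start, end) {
  data.frame(target_id = target_id, class = class, start = start, end = end)
}

# random ternary labels and rounded scores on a coarse value grid (to
# force ties), for oracle comparisons
randomLabelledScores <- function(n, nLevels = 25L, maskFrac = 0) {
  labels <- sample(c(0L, 1L), n, replace = TRUE)
  if (maskFrac > 0)
    labels[sample.int(n, round(maskFrac * n))] <- NA_integer_
  scores <- roundHalfUp(sample(seq(0, nLevels) / nLevels, n, replace = TRUE))
  list(labels = labels, scores = scores)
}

# brute-force F1 maximum over all distinct rounded score values used as
# thresholds (score >= threshold rule) -- independent of the grid scan
bruteForceFmax <- function(labels, scores) {
  keep <- !is.na(labels)
  l <- labels[keep]; s <- scores[keep]
  best <- 0
  for (thr in unique(s)) {
    pred <- s >= thr - 1e-9
    tp <- sum(l == 1L & pred); fp <- sum(l == 0L & pred)
    fn <- sum(l == 1L & !pred)
    den <- 2 * tp + fp + fn
    f1 <- if (den > 0) 2 * tp / den else 0
    if (f1 > best) best <- f1
  }
  best
}

# rank-statistic (Mann-Whitney with tie correction) AUC, an oracle
# independent of the ROC trapezoid
rankAuc <- function(labels, scores) {
  keep <- !is.na(labels)
  l <- labels[keep]; s <- scores[keep]
  P <- sum(l == 1L); N <- sum(l == 0L)
  r <- rank(s)
  (sum(r[l == 1L]) - P * (P + 1) / 2) / (P * N)
}

# wrap flat labels/scores into single-target reference + prediction sets
wrapSets <- function(labels, scores, methodName = "toy",
                     declaredThreshold = 0.5, nTargets = 1L) {
  cuts <- sort(rep_len(seq_len(nTargets), length(labels)))
  labs <- split(labels, cuts)
  scos <- split(scores, cuts)
  names(labs) <- names(scos) <- sprintf("T%03d", seq_len(nTargets))
  mode <- if (anyNA(labels)) "disprot_pdb" else "disprot"
  ref <- new("ReferenceSet", mode = mode,
             labels = IRanges::IntegerList(labs), provenance = "test")
  pset <- resolveThreshold(newPredictionSet(methodName, scos,
                                            declaredThreshold = declaredThreshold))
  list(ref = ref, pset = pset)
}
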