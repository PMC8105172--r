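# Binned representation: counts of positive- and negative-labelled residues
# at each of the 1001 representable rounded score values. All curve and
# bootstrap machinery operates on these bins; with 3-decimal rounding the
# representation is lossless.
.scoreBins <- function(labels, scores) {
  keep <- !is.na(labels)
  ms <- .milli(scores[keep]) + 1L   # 1-indexed bins 1..1001
  lb <- labels[keep]
  list(pos = tabulate(ms[lb == 1L], nbins = 1001L),
       neg = tabulate(ms[lb == 0L], nbins = 1001L),
       masked = sum(!keep))
}

# lowest bin index (1-based) classified positive under score >= threshold
.thresholdBin <- function(threshold) {
  as.integer(ceiling(threshold * 1000 - 1e-6)) + 1L
}

#' Confusion matrix of a prediction against a reference
#'
#' Counts TP/FP/FN/TN over unmasked residues; masked residues contribute
#' only to the masked count. States are obtained by applying the resolved
#' threshold to the rounded scores (`score >= threshold`).
#'
#' @param ref a [ReferenceSet-class], or a list/vector of ternary labels
#'   (1 positive, 0 negative, NA masked).
#' @param pred a [PredictionSet-class] (resolved via [resolveThreshold()]
#'   if needed), or a parallel list/vector of binary states.
#' @param perTarget return a named list of per-target matrices instead of
#'   the dataset matrix.
#' @param allowMissing see [alignPrediction()].
#' @return a [ConfusionMatrix-class], or a named list of them.
#' @export
confusion <- function(ref, pred, perTarget = FALSE, allowMissing = FALSE) {
  if (is(ref, "ReferenceSet") && is(pred, "PredictionSet")) {
    if (is.na(pred@effectiveThreshold)) pred <- resolveThreshold(pred)
    al <- alignPrediction(pred, ref, allowMissing = allowMissing)
    labs <- as.list(al$ref@labels)
    sts <- lapply(as.list(roundScores(al$pset)@scores),
                  function(x) as.integer(.classify(x, al$pset@effectiveThreshold)))
  } else {
    labs <- if (is.list(ref)) ref else list(ref)
    sts <- if (is.list(pred)) pred else list(pred)
    if (length(labs) != length(sts))
      .stopf("reference and prediction lists differ in length")
    if (is.null(names(labs))) names(labs) <- paste0("t", seq_along(labs))
    names(sts) <- names(labs)
  }
  one <- function(lab, st, tid) {
    if (length(lab) != length(st))
      .stopf("length mismatch for target %s: %d labels vs %d states",
             tid, length(lab), length(st))
    keep <- !is.na(lab)
    l <- lab[keep]; s <- st[keep]
    new("ConfusionMatrix",
        tp = sum(l == 1L & s == 1L), fp = sum(l == 0L & s == 1L),
        fn = sum(l == 1L & s == 0L), tn = sum(l == 0L & s == 0L),
        masked = sum(!keep))
  }
  cms <- Map(one, labs, sts, names(labs))
  if (perTarget) return(cms)
  Reduce(addConfusion, cms,
         new("ConfusionMatrix", tp = 0, fp = 0, fn = 0, tn = 0, masked = 0))
}

#' @rdname confusion
#' @param a,b [ConfusionMatrix-class] objects to sum cellwise.
#' @export
addConfusion <- function(a, b) {
  new("ConfusionMatrix", tp = a@tp + b@tp, fp = a@fp + b@fp,
      fn = a@fn + b@fn, tn = a@tn + b@tn, masked = a@masked + b@masked)
}

#' Point evaluation metrics with zero-denominator conventions
#'
#' Standard binary classification metrics. Conventions for degenerate
#' denominators: F-beta (0.5, 1, 2) are 0 if their denominator is 0; MCC
#' is 0 whenever any of the four marginals (predicted positives, predicted
#' negatives, reference positives, reference negatives) is 0; simple rates
#' (TPR, TNR, PPV, FPR) are 0 on a zero denominator. BAC is the mean of
#' TPR and TNR. Which conventions fired is recorded in the
#' `"conventions"` attribute.
#'
#' @param cm a [ConfusionMatrix-class] (or named vector with tp/fp/fn/tn).
#' @return named numeric vector: `mcc`, `f1`, `f05`, `f2`, `tnr`, `tpr`,
#'   `ppv`, `fpr`, `bac`.
#' @export
#' @examples
#' cm <- new("ConfusionMatrix", tp = 26, fp = 16, fn = 19, tn = 585,
#'           masked = 0)
#' round(pointMetrics(cm), 3)
pointMetrics <- function(cm) {
  if (is(cm, "ConfusionMatrix")) {
    tp <- cm@tp; fp <- cm@fp; fn <- cm@fn; tn <- cm@tn
  } else {
    tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  }
  pp <- tp + fp; pn <- fn + tn; rp <- tp + fn; rn <- fp + tn
  fired <- character()
  fbeta <- function(beta) {
    den <- (1 + beta^2) * tp + beta^2 * fn + fp
    if (den == 0) { fired <<- c(fired, sprintf("f%g", beta)); 0 }
    else (1 + beta^2) * tp / den
  }
  mcc <- if (pp == 0 || pn == 0 || rp == 0 || rn == 0) {
    fired <- c(fired, "mcc"); 0
  } else (tp * tn - fp * fn) / sqrt(pp) / sqrt(pn) / sqrt(rp) / sqrt(rn)
  rate <- function(num, den, nm) {
    if (den == 0) { fired <<- c(fired, nm); 0 } else num / den
  }
  tpr <- rate(tp, rp, "tpr"); tnr <- rate(tn, rn, "tnr")
  ppv <- rate(tp, pp, "ppv"); fpr <- rate(fp, rn, "fpr")
  out <- c(mcc = mcc, f1 = fbeta(1), f05 = fbeta(0.5), f2 = fbeta(2),
           tnr = tnr, tpr = tpr, ppv = ppv, fpr = fpr,
           bac = (tpr + tnr) / 2)
  attr(out, "conventions") <- unique(fired)
  out
}

# per-threshold metric columns from score bins (vectorized over the grid)
.curveColumns <- function(pos, neg) {
  P <- sum(pos); N <- sum(neg)
  tp <- rev(cumsum(rev(pos)))   # tp[t] = positives with bin >= t
  fp <- rev(cumsum(rev(neg)))
  fn <- P - tp; tn <- N - fp
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = .ratio0(tp, tp + fp),
       recall    = .ratio0(tp, P),
       tpr       = .ratio0(tp, P),
       fpr       = .ratio0(fp, N),
       f1        = .ratio0(2 * tp, 2 * tp + fp + fn))
}

.trapezoidAuc <- function(fpr, tpr) {
  # threshold ascends -> fpr descends; append (0,0) and (1,1) endpoints
  x <- c(0, rev(fpr), 1)
  y <- c(0, rev(tpr), 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

.curveSetFromColumns <- function(precision, recall, tpr, fpr, f1, strategy) {
  thr <- thresholdGrid()
  fmax <- max(f1)
  new("CurveSet",
      curve = data.frame(threshold = thr, precision = precision,
                         recall = recall, tpr = tpr, fpr = fpr, f1 = f1),
      fMax = fmax,
      fMaxThreshold = thr[which(f1 >= fmax - 1e-12)[1L]],
      auc = min(1, max(0, .trapezoidAuc(fpr, tpr))),
      strategy = strategy)
}

#' Threshold curves, F_max and ROC AUC
#'
#' Evaluates a prediction against a reference at every threshold of the
#' fixed grid (step 0.001, `score >= threshold`), excluding masked
#' residues. Under the `dataset` strategy one confusion matrix per
#' threshold is computed over the concatenated residues of all targets;
#' under the `target` strategy the metric values are computed per target
#' and their unweighted mean is taken per threshold. F_max is the maximum
#' F1 over the grid (ties resolved to the lowest threshold) and AUC is the
#' trapezoidal area under the ROC points augmented with (0,0) and (1,1).
#'
#' @inheritParams confusion
#' @param strategy `"dataset"` or `"target"`.
#' @return a [CurveSet-class].
#' @export
computeCurves <- function(ref, pred, strategy = c("dataset", "target"),
                          allowMissing = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(is(ref, "ReferenceSet"), is(pred, "PredictionSet"))
  al <- alignPrediction(roundScores(pred), ref, allowMissing = allowMissing)
  labs <- as.list(al$ref@labels)
  scos <- as.list(al$pset@scores)
  if (strategy == "dataset") {
    b <- .scoreBins(unlist(labs, use.names = FALSE),
                    unlist(scos, use.names = FALSE))
    cc <- .curveColumns(b$pos, b$neg)
    return(.curveSetFromColumns(cc$precision, cc$recall, cc$tpr, cc$fpr,
                                cc$f1, "dataset"))
  }
  acc <- matrix(0, nrow = 1001L, ncol = 5L)
  for (i in seq_along(labs)) {
    b <- .scoreBins(labs[[i]], scos[[i]])
    cc <- .curveColumns(b$pos, b$neg)
    acc <- acc + cbind(cc$precision, cc$recall, cc$tpr, cc$fpr, cc$f1)
  }
  acc <- acc / length(labs)
  .curveSetFromColumns(acc[, 1L], acc[, 2L], acc[, 3L], acc[, 4L],
                       acc[, 5L], "target")
}

# metric value from bins at a fixed threshold bin, or curve-level summary
.metricFromBins <- function(pos, neg, metric, thresholdBin) {
  if (metric %in% c("fmax", "auc")) {
    cc <- .curveColumns(pos, neg)
    if (metric == "fmax") return(max(cc$f1))
    return(min(1, max(0, .trapezoidAuc(cc$fpr, cc$tpr))))
  }
  idx <- thresholdBin:1001L
  tp <- sum(pos[idx]); fp <- sum(neg[idx])
  fn <- sum(pos) - tp; tn <- sum(neg) - fp
  unname(pointMetrics(c(tp = tp, fp = fp, fn = fn, tn = tn))[metric])
}

#' Residue-level bootstrap of an evaluation metric
#'
#' Resamples the concatenated (label, score) residue pairs of the whole
#' dataset with replacement `nReplicates` times and recomputes the metric
#' on each replicate. Resampling is performed as a multinomial draw over
#' the distinct (label, rounded-score) cells, which is distributionally
#' identical to resampling the individual residues. The confidence
#' interval is the replicate mean plus/minus
#' `qt(1 - alpha/2, nReplicates - 1)` times the replicate standard
#' deviation (denominator n - 1). Metrics undefined on a replicate take
#' their zero-denominator convention value; the number of such replicates
#' is attached as attribute `"degenerateReplicates"`.
#'
#' @inheritParams confusion
#' @param metric one of `"f1"`, `"f05"`, `"f2"`, `"mcc"`, `"bac"`,
#'   `"tpr"`, `"tnr"`, `"ppv"`, `"fpr"` (evaluated at the resolved
#'   threshold), or `"fmax"`, `"auc"` (curve summaries).
#' @param nReplicates number of bootstrap replicates (default 1000).
#' @param seed integer seed; reproducible bit-for-bit for a given seed.
#' @param alpha two-sided significance level.
#' @return a [BootstrapResult-class].
#' @export
bootstrapMetric <- function(ref, pred, metric = "f1", nReplicates = 1000L,
                            seed = 1L, alpha = 0.05, allowMissing = FALSE) {
  metric <- match.arg(metric, c("f1", "f05", "f2", "mcc", "bac", "tpr",
                                "tnr", "ppv", "fpr", "fmax", "auc"))
  stopifnot(is(ref, "ReferenceSet"), is(pred, "PredictionSet"))
  if (is.na(pred@effectiveThreshold)) pred <- resolveThreshold(pred)
  al <- alignPrediction(roundScores(pred), ref, allowMissing = allowMissing)
  b <- .scoreBins(unlist(as.list(al$ref@labels), use.names = FALSE),
                  unlist(as.list(al$pset@scores), use.names = FALSE))
  n <- sum(b$pos) + sum(b$neg)
  if (n < 2L) .stopf("bootstrap requires at least 2 unmasked residues")
  tb <- .thresholdBin(al$pset@effectiveThreshold)
  point <- .metricFromBins(b$pos, b$neg, metric, tb)
  cells <- c(b$pos, b$neg)
  set.seed(seed)
  draws <- stats::rmultinom(nReplicates, size = n, prob = cells / n)
  degenerate <- 0L
  reps <- vapply(seq_len(nReplicates), function(j) {
    pos <- draws[1:1001, j]; neg <- draws[1002:2002, j]
    v <- .metricFromBins(pos, neg, metric, tb)
    v
  }, numeric(1))
  # degenerate replicates: no positive or no negative labels drawn
  degenerate <- sum(colSums(draws[1:1001, , drop = FALSE]) == 0L |
                      colSums(draws[1002:2002, , drop = FALSE]) == 0L)
  m <- mean(reps); s <- stats::sd(reps)
  half <- stats::qt(1 - alpha / 2, df = nReplicates - 1L) * s
  out <- new("BootstrapResult", metric = metric, pointEstimate = point,
             replicates = reps, ciLow = m - half, ciHigh = m + half,
             alpha = alpha)
  attr(out, "degenerateReplicates") <- degenerate
  out
}

#' Two-tailed paired comparison of two methods
#'
#' Paired two-tailed Student t-test over parallel per-replicate (or
#' per-target) metric values of two methods. With zero variance of the
#' differences the p-value degenerates: 1 when the means are equal, 0
#' otherwise (flagged via attribute `"degenerate"`).
#'
#' @param x,y equal-length metric value vectors (n >= 2).
#' @param paired paired test (default) or two-sample Welch test.
#' @return two-sided p-value in \[0, 1\].
#' @export
compareMethods <- function(x, y, paired = TRUE) {
  if (length(x) != length(y) && paired)
    .stopf("paired comparison needs equal-length vectors")
  if (length(x) < 2L || length(y) < 2L)
    .stopf("comparison needs at least 2 values per method")
  if (paired) {
    d <- x - y
    if (stats::sd(d) == 0) {
      p <- if (isTRUE(all.equal(mean(d), 0))) 1 else 0
      attr(p, "degenerate") <- TRUE
      return(p)
    }
    return(stats::t.test(x, y, paired = TRUE)$p.value)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  stats::t.test(x, y)$p.value
}
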