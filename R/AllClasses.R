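#' @importFrom methods new validObject is setClass setGeneric setMethod show
#' @importClassesFrom IRanges IntegerList NumericList
#' @import S4Vectors
NULL

.REFERENCE_MODES <- c("disprot", "disprot_pdb", "binding")
.ANNOTATION_CLASSES <- c("disorder", "binding", "structure_observed")

#' ReferenceSet: per-residue ternary labels for a set of targets
#'
#' Holds, for every target protein, one label per residue: `1L` (positive),
#' `0L` (negative) or `NA` (masked, excluded from all metrics). Three modes
#' exist. In `disprot` mode positives are disorder-annotated residues and
#' everything else is negative. In `disprot_pdb` mode positives are
#' disorder-annotated residues (disorder always overwrites structure),
#' negatives are structure-observed residues not annotated as disordered,
#' and all remaining residues are masked. In `binding` mode positives are
#' binding-annotated residues and everything else is negative; targets
#' without any binding annotation are retained as all-negative entries.
#'
#' @slot mode character, one of `"disprot"`, `"disprot_pdb"`, `"binding"`.
#' @slot labels [IRanges::IntegerList] of per-residue labels, named by
#'   target identifier.
#' @slot provenance free-text build record.
#' @seealso [buildReference()], [referenceComposition()]
#' @export
setClass("ReferenceSet",
  representation(mode = "character", labels = "IntegerList",
                 provenance = "character"))

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (length(object@mode) != 1L || !object@mode %in% .REFERENCE_MODES)
    msg <- c(msg, sprintf("mode must be one of %s",
                          paste(.REFERENCE_MODES, collapse = ", ")))
  if (length(object@labels) > 0L) {
    if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
      msg <- c(msg, "labels must be uniquely named by target_id")
    v <- unlist(object@labels, use.names = FALSE)
    if (!all(v %in% c(0L, 1L, NA_integer_)))
      msg <- c(msg, "labels must be 0, 1 or NA (masked)")
    if (length(msg) == 0L && object@mode %in% c("disprot", "binding") &&
        anyNA(v))
      msg <- c(msg, sprintf("mode '%s' admits no masked residues",
                            object@mode))
  }
  if (length(msg)) msg else TRUE
})

#' PredictionSet: per-residue scores and states for one method
#'
#' Per-residue predictor output for a set of targets: a score in \[0, 1\]
#' per residue and, optionally, a binary state per residue. A declared
#' decision threshold may accompany the scores; the effective threshold
#' used for evaluation is resolved by [resolveThreshold()].
#'
#' @slot methodName method label used in reports.
#' @slot scores [IRanges::NumericList] of per-residue scores in \[0, 1\],
#'   named by target identifier.
#' @slot states [IRanges::IntegerList] of per-residue binary states; empty
#'   when the method emits scores only.
#' @slot declaredThreshold threshold declared by the method authors
#'   (`NA_real_` when absent).
#' @slot effectiveThreshold resolved threshold (`NA_real_` until
#'   [resolveThreshold()] has been applied).
#' @export
setClass("PredictionSet",
  representation(methodName = "character", scores = "NumericList",
                 states = "IntegerList", declaredThreshold = "numeric",
                 effectiveThreshold = "numeric"))

setValidity("PredictionSet", function(object) {
  msg <- character()
  if (length(object@methodName) != 1L)
    msg <- c(msg, "methodName must be a single string")
  s <- unlist(object@scores, use.names = FALSE)
  if (length(s) && (anyNA(s) || min(s) < 0 || max(s) > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (length(object@states) > 0L) {
    if (!identical(lengths(object@states, use.names = FALSE),
                   lengths(object@scores, use.names = FALSE)) ||
        !identical(names(object@states), names(object@scores)))
      msg <- c(msg, "states must parallel scores per target")
    st <- unlist(object@states, use.names = FALSE)
    if (length(st) && !all(st %in% c(0L, 1L)))
      msg <- c(msg, "states must be 0 or 1")
  }
  for (slot in c("declaredThreshold", "effectiveThreshold")) {
    v <- slot(object, slot)
    if (length(v) != 1L || (!is.na(v) && (v < 0 || v > 1)))
      msg <- c(msg, sprintf("%s must be a single value in [0, 1] or NA", slot))
  }
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: binary classification counts plus masked residues
#'
#' @slot tp,fp,fn,tn non-negative counts.
#' @slot masked count of residues excluded from evaluation by masking.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric", masked = "numeric"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn, object@masked)
  if (length(v) != 5L || anyNA(v) || any(v < 0))
    "tp, fp, fn, tn, masked must be single non-negative counts"
  else TRUE
})

#' CurveSet: per-threshold evaluation curves with F_max and AUC
#'
#' Evaluation at every threshold of the fixed grid (step 0.001 on
#' \[0, 1\], `score >= threshold` rule). Holds the precision-recall and
#' ROC coordinates per threshold, the maximum F1 over the grid (F_max),
#' the lowest threshold attaining it, and the trapezoidal ROC AUC with
#' endpoints (0,0) and (1,1) appended.
#'
#' @slot curve data.frame with columns `threshold`, `precision`, `recall`,
#'   `tpr`, `fpr`, `f1`.
#' @slot fMax maximum F1 over the grid.
#' @slot fMaxThreshold lowest threshold attaining `fMax`.
#' @slot auc area under the ROC curve.
#' @slot strategy `"dataset"` (concatenated residues) or `"target"`
#'   (unweighted mean of per-target metrics).
#' @export
setClass("CurveSet",
  representation(curve = "data.frame", fMax = "numeric",
                 fMaxThreshold = "numeric", auc = "numeric",
                 strategy = "character"))

setValidity("CurveSet", function(object) {
  msg <- character()
  need <- c("threshold", "precision", "recall", "tpr", "fpr", "f1")
  if (!all(need %in% names(object@curve)))
    msg <- c(msg, "curve must have threshold/precision/recall/tpr/fpr/f1")
  if (!object@strategy %in% c("dataset", "target"))
    msg <- c(msg, "strategy must be 'dataset' or 'target'")
  if (length(object@auc) != 1L || is.na(object@auc) ||
      object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' BootstrapResult: residue-level bootstrap of an evaluation metric
#'
#' @slot metric name of the bootstrapped metric.
#' @slot pointEstimate metric value on the full dataset.
#' @slot replicates metric values over the bootstrap replicates.
#' @slot ciLow,ciHigh Student-t confidence bounds
#'   (replicate mean +/- t(1 - alpha/2, B - 1) * replicate SD).
#' @slot alpha two-sided significance level (default 0.05).
#' @export
setClass("BootstrapResult",
  representation(metric = "character", pointEstimate = "numeric",
                 replicates = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", alpha = "numeric"))

setValidity("BootstrapResult", function(object) {
  if (object@ciLow > object@ciHigh + 1e-12)
    "ciLow must not exceed ciHigh"
  else TRUE
})

setMethod("show", "ReferenceSet", function(object) {
  comp <- referenceComposition(object)
  cat(sprintf("ReferenceSet (mode=%s): %d targets, %d residues\n",
              object@mode, length(object@labels), comp$total))
  cat(sprintf("  positives %d | negatives %d | masked %d\n",
              comp$positives, comp$negatives, comp$masked))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet '%s': %d targets, %d residues\n",
              object@methodName, length(object@scores),
              sum(lengths(object@scores))))
  cat(sprintf("  states: %s | declared threshold: %s | effective: %s\n",
              if (length(object@states)) "present" else "absent",
              format(object@declaredThreshold),
              format(object@effectiveThreshold)))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP=%g FP=%g FN=%g TN=%g (masked %g)\n",
              object@tp, object@fp, object@fn, object@tn, object@masked))
})

setMethod("show", "CurveSet", function(object) {
  cat(sprintf(
    "CurveSet (%s strategy): F_max=%.3f at threshold %.3f, AUC=%.3f\n",
    object@strategy, object@fMax, object@fMaxThreshold, object@auc))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult [%s]: %.4f (%d replicates, %g%% CI %.4f-%.4f)\n",
              object@metric, object@pointEstimate, length(object@replicates),
              100 * (1 - object@alpha), object@ciLow, object@ciHigh))
})
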