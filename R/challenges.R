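#' Published fully-disordered-protein benchmark table
#'
#' Confusion matrices (TN, FP, FN, TP over 646 target proteins) and the
#' published metric values (MCC, F1, TNR, TPR, PPV, BAC, printed to three
#' decimals) for 33 disorder predictors and naive baselines on the
#' fully-disordered-protein challenge of a community blind assessment.
#' Shipped as exact worked examples for [pointMetrics()].
#'
#' @return data.frame with columns `method`, `tn`, `fp`, `fn`, `tp`,
#'   `mcc`, `f1`, `tnr`, `tpr`, `ppv`, `bac`.
#' @export
idpBenchmarkTable <- function() {
  path <- system.file("extdata", "idp_benchmark_table.tsv",
                      package = "DisorderBench", mustWork = TRUE)
  utils::read.delim(path, check.names = TRUE)
}

#' Fully-disordered-protein (IDP) challenge
#'
#' Protein-level classification challenge: a target counts as a fully
#' disordered protein when at least `idpThreshold` (default 95%) of its
#' residues are annotated — respectively predicted — as disordered.
#' Annotated fractions come from a disorder-mode reference; predicted
#' fractions from each method's binary states at its resolved threshold.
#' Per method, targets are tallied into a protein-level confusion matrix
#' and scored with [pointMetrics()]; methods are ranked by F1 (ties broken
#' by method name).
#'
#' @param ref a [ReferenceSet-class] in `disprot` mode.
#' @param predictions list of [PredictionSet-class] objects.
#' @param idpThreshold minimum disordered fraction for an IDP call.
#' @param allowMissing see [alignPrediction()].
#' @return list with `ranking` (one row per method: counts plus metrics,
#'   sorted by F1) and `calls` (per-method data.frame of per-target
#'   fractions and IDP calls).
#' @export
idpChallenge <- function(ref, predictions, idpThreshold = 0.95,
                         allowMissing = FALSE) {
  stopifnot(is(ref, "ReferenceSet"))
  if (ref@mode != "disprot")
    .stopf("IDP challenge requires a disprot-mode reference")
  if (is(predictions, "PredictionSet")) predictions <- list(predictions)
  annFrac <- vapply(as.list(ref@labels),
                    function(x) mean(x == 1L), numeric(1))
  calls <- list()
  rows <- lapply(predictions, function(pset) {
    pset <- resolveThreshold(pset)
    al <- alignPrediction(pset, ref, allowMissing = allowMissing)
    sts <- al$pset@states
    predFrac <- vapply(as.list(sts), function(x) mean(x == 1L), numeric(1))
    af <- annFrac[names(predFrac)]
    annIdp <- af >= idpThreshold
    predIdp <- predFrac >= idpThreshold
    calls[[pset@methodName]] <<- data.frame(
      target_id = names(predFrac), annotated_fraction = unname(af),
      predicted_fraction = unname(predFrac),
      annotated_idp = unname(annIdp), predicted_idp = unname(predIdp),
      row.names = NULL)
    cm <- new("ConfusionMatrix",
              tp = sum(annIdp & predIdp), fp = sum(!annIdp & predIdp),
              fn = sum(annIdp & !predIdp), tn = sum(!annIdp & !predIdp),
              masked = 0)
    m <- pointMetrics(cm)
    data.frame(method = pset@methodName, tn = cm@tn, fp = cm@fp,
               fn = cm@fn, tp = cm@tp, mcc = m[["mcc"]], f1 = m[["f1"]],
               tnr = m[["tnr"]], tpr = m[["tpr"]], ppv = m[["ppv"]],
               bac = m[["bac"]], idp_threshold = idpThreshold,
               row.names = NULL)
  })
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$f1, ranking$method), , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, calls = calls)
}

.readPredictionDir <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  sets <- list()
  exclusions <- character()
  for (f in files) {
    p <- tryCatch(suppressWarnings(readPredictions(f)),
                  error = function(e) {
                    message(sprintf("skipping unreadable prediction file %s: %s",
                                    f, conditionMessage(e)))
                    NULL
                  })
    if (is.null(p) || length(p@scores) == 0L) exclusions <- c(exclusions, f)
    else sets[[p@methodName]] <- p
  }
  list(sets = sets, exclusions = exclusions)
}

#' Run a full residue-level challenge
#'
#' Orchestrates the evaluation of one reference set against any number of
#' prediction sets: per method, dataset- and target-strategy curves
#' ([computeCurves()]), point metrics at the resolved threshold, a
#' bootstrap confidence interval ([bootstrapMetric()]) and, across
#' methods, a pairwise two-tailed p-value matrix from the paired
#' per-replicate bootstrap values ([compareMethods()]). Methods are ranked
#' by dataset-strategy F_max (ties broken by method name). Deterministic
#' for a given seed.
#'
#' @param ref a [ReferenceSet-class].
#' @param predictions list of [PredictionSet-class] objects, or a
#'   directory of prediction files (unreadable files are skipped, logged
#'   and listed under `exclusions`).
#' @param bootMetric metric to bootstrap (see [bootstrapMetric()]).
#' @param nReplicates bootstrap replicate count.
#' @param seed integer seed driving every stochastic step.
#' @param allowMissing see [alignPrediction()].
#' @return list with `ranking` (data.frame), `curves` (per method, list
#'   with `dataset` and `target` [CurveSet-class]s), `metrics` (per-method
#'   named vectors), `bootstrap` (per-method [BootstrapResult-class]),
#'   `pvalues` (matrix), `exclusions`, `mode`, `seed`.
#' @export
runChallenge <- function(ref, predictions, bootMetric = "f1",
                         nReplicates = 1000L, seed = 1L,
                         allowMissing = FALSE) {
  stopifnot(is(ref, "ReferenceSet"))
  exclusions <- character()
  if (is.character(predictions) && length(predictions) == 1L &&
      dir.exists(predictions)) {
    rd <- .readPredictionDir(predictions)
    predictions <- rd$sets
    exclusions <- rd$exclusions
  }
  if (is(predictions, "PredictionSet")) predictions <- list(predictions)
  if (length(predictions) == 0L) .stopf("no readable prediction sets")
  nms <- vapply(predictions, methodName, character(1))
  names(predictions) <- nms
  predictions <- predictions[order(nms)]
  curves <- list(); metrics <- list(); boots <- list()
  rows <- list()
  for (i in seq_along(predictions)) {
    pset <- resolveThreshold(predictions[[i]])
    nm <- pset@methodName
    cd <- computeCurves(ref, pset, "dataset", allowMissing = allowMissing)
    ct <- computeCurves(ref, pset, "target", allowMissing = allowMissing)
    cm <- confusion(ref, pset, allowMissing = allowMissing)
    pm <- pointMetrics(cm)
    bs <- bootstrapMetric(ref, pset, metric = bootMetric,
                          nReplicates = nReplicates, seed = seed + i,
                          allowMissing = allowMissing)
    curves[[nm]] <- list(dataset = cd, target = ct)
    metrics[[nm]] <- pm
    boots[[nm]] <- bs
    rows[[nm]] <- data.frame(
      method = nm, reference_mode = ref@mode, strategy = "dataset",
      threshold = pset@effectiveThreshold,
      f_max = cd@fMax, f_max_threshold = cd@fMaxThreshold, auc = cd@auc,
      f_max_target = ct@fMax, auc_target = ct@auc,
      mcc = pm[["mcc"]], f1 = pm[["f1"]], f05 = pm[["f05"]],
      f2 = pm[["f2"]], tnr = pm[["tnr"]], tpr = pm[["tpr"]],
      ppv = pm[["ppv"]], fpr = pm[["fpr"]], bac = pm[["bac"]],
      boot_metric = bootMetric, ci_low = bs@ciLow, ci_high = bs@ciHigh,
      row.names = NULL)
  }
  ranking <- do.call(rbind, rows)
  key <- roundHalfUp(ranking$f_max, 3L)
  ranking <- ranking[order(-key, ranking$method), , drop = FALSE]
  rownames(ranking) <- NULL
  nm <- names(predictions)
  pv <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (a in nm) for (b in nm)
    pv[a, b] <- if (a == b) 1 else
      as.numeric(compareMethods(boots[[a]]@replicates, boots[[b]]@replicates))
  list(ranking = ranking, curves = curves, metrics = metrics,
       bootstrap = boots, pvalues = pv, exclusions = exclusions,
       mode = ref@mode, seed = seed)
}

#' Evaluate on a subset of targets
#'
#' Restricts the reference (and thereby every prediction) to a target
#' subset — e.g. a taxonomic partition supplied by the user — and runs
#' the identical challenge machinery on the restriction.
#'
#' @inheritParams runChallenge
#' @param ids non-empty subset of reference target identifiers.
#' @return as [runChallenge()].
#' @export
subsetEvaluation <- function(ref, predictions, ids, ...) {
  runChallenge(subsetReference(ref, ids), predictions, ...)
}

#' Write a challenge report bundle to disk
#'
#' Emits `ranking.tsv` and `ranking.json`, per-method curve tables
#' `curves_<method>_<strategy>.tsv` (threshold, precision, recall, tpr,
#' fpr, f1), `pvalues.tsv` and `exclusions.txt` under `dir`. Every row is
#' self-describing: it carries the strategy, reference mode and threshold
#' that produced it.
#'
#' @param report a [runChallenge()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$ranking, file.path(dir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$ranking, file.path(dir, "ranking.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (nm in names(report$curves)) {
    for (strat in c("dataset", "target")) {
      cs <- report$curves[[nm]][[strat]]
      tab <- cbind(method = nm, reference_mode = report$mode,
                   strategy = strat, cs@curve)
      safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
      utils::write.table(tab,
                         file.path(dir, sprintf("curves_%s_%s.tsv", safe,
                                                strat)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  pv <- data.frame(method = rownames(report$pvalues), report$pvalues,
                   check.names = FALSE)
  utils::write.table(pv, file.path(dir, "pvalues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(report$exclusions, file.path(dir, "exclusions.txt"))
  invisible(dir)
}
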