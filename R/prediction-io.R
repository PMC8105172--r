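#' Construct a PredictionSet from in-memory vectors
#'
#' @param methodName method label.
#' @param scores named list (or `NumericList`) of per-residue scores in
#'   \[0, 1\].
#' @param states optional named list of per-residue binary states,
#'   parallel to `scores`.
#' @param declaredThreshold optional author-declared threshold.
#' @return a [PredictionSet-class]; the effective threshold is unresolved.
#' @export
newPredictionSet <- function(methodName, scores, states = NULL,
                             declaredThreshold = NA_real_) {
  scores <- IRanges::NumericList(scores)
  states <- if (is.null(states) || length(states) == 0L)
    IRanges::IntegerList() else IRanges::IntegerList(lapply(states, as.integer))
  new("PredictionSet", methodName = as.character(methodName),
      scores = scores, states = states,
      declaredThreshold = as.numeric(declaredThreshold),
      effectiveThreshold = NA_real_)
}

#' Read a per-residue prediction file
#'
#' The community per-residue tab format: each entry starts with a
#' `>target_id` line, followed by one line per residue with tab-separated
#' fields `position`, `residue`, `score`, `state`. The score and state
#' columns are individually optional: three fields mean
#' position/residue/score; state-only files carry four fields with an
#' empty score field. Positions must be consecutive from 1. When the score
#' column is absent, states are copied into scores verbatim.
#'
#' @param path prediction file.
#' @param methodName method label; defaults to the file name without
#'   extension.
#' @return a [PredictionSet-class] (threshold not yet resolved). An empty
#'   file yields an empty set with a warning.
#' @export
readPredictions <- function(path, methodName = NULL) {
  if (is.null(methodName))
    methodName <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    .warnf("empty prediction file: %s", path)
    return(newPredictionSet(methodName, list()))
  }
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L || hdr[1L] != 1L)
    .stopf("prediction file %s must start with a '>' header", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  if (anyDuplicated(ids))
    .stopf("duplicate prediction entries for target(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bounds <- cbind(hdr + 1L, c(hdr[-1L] - 1L, length(lines)))
  scores <- vector("list", length(ids))
  states <- vector("list", length(ids))
  anyScore <- FALSE
  anyState <- FALSE
  for (i in seq_along(ids)) {
    if (bounds[i, 1L] > bounds[i, 2L])
      .stopf("target %s has no residue lines", ids[i])
    body <- lines[bounds[i, 1L]:bounds[i, 2L]]
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 2L))
      .stopf("target %s: malformed residue line '%s'", ids[i],
             body[which(nf < 2L)[1L]])
    pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    if (anyNA(pos) || !identical(pos, seq_along(pos)))
      .stopf("target %s: positions must be consecutive from 1", ids[i])
    sco <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "",
                  character(1))
    sta <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "",
                  character(1))
    hasScore <- any(nzchar(sco))
    hasState <- any(nzchar(sta))
    if (!hasScore && !hasState)
      .stopf("target %s: neither score nor state column present", ids[i])
    if (hasState) {
      sv <- suppressWarnings(as.integer(sta))
      if (anyNA(sv) || !all(sv %in% 0:1))
        .stopf("target %s: states must be 0 or 1", ids[i])
      states[[i]] <- sv
      anyState <- TRUE
    }
    if (hasScore) {
      xv <- suppressWarnings(as.numeric(sco))
      if (anyNA(xv))
        .stopf("target %s: unreadable score at position %d", ids[i],
               which(is.na(xv))[1L])
      if (min(xv) < 0 || max(xv) > 1)
        .stopf("target %s: score %g at position %d outside [0, 1]", ids[i],
               xv[which(xv < 0 | xv > 1)[1L]], which(xv < 0 | xv > 1)[1L])
      scores[[i]] <- xv
      anyScore <- TRUE
    } else {
      # scores missing: states are used as scores
      scores[[i]] <- as.numeric(states[[i]])
    }
  }
  names(scores) <- ids
  if (anyState) {
    # states must parallel scores set-wide; entries lacking a state column
    # in a file that has states elsewhere are derived later at resolution
    miss <- vapply(states, is.null, logical(1))
    if (any(miss))
      .stopf("state column present for some targets but missing for: %s",
             paste(ids[miss], collapse = ", "))
    names(states) <- ids
  } else states <- NULL
  newPredictionSet(methodName, scores, states)
}

#' Write a PredictionSet in the per-residue tab format
#'
#' Scores are written with exactly three decimals. When states are absent
#' only three columns are emitted; when scores were copied from states the
#' full four-column form is still written.
#'
#' @param pset a [PredictionSet-class].
#' @param path output file.
#' @param sequences optional named [Biostrings::AAStringSet] supplying the
#'   residue-letter column; `X` is written when absent.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(pset, path, sequences = NULL) {
  stopifnot(is(pset, "PredictionSet"))
  con <- file(path, "w")
  on.exit(close(con))
  hasStates <- length(pset@states) > 0L
  for (tid in names(pset@scores)) {
    sc <- pset@scores[[tid]]
    aa <- if (!is.null(sequences) && tid %in% names(sequences))
      strsplit(as.character(sequences[[tid]]), "")[[1L]]
    else rep("X", length(sc))
    lines <- if (hasStates)
      sprintf("%d\t%s\t%.3f\t%d", seq_along(sc), aa, sc, pset@states[[tid]])
    else
      sprintf("%d\t%s\t%.3f", seq_along(sc), aa, sc)
    writeLines(c(paste0(">", tid), lines), con)
  }
  invisible(path)
}

#' Round prediction scores to three decimals (half-up)
#'
#' Rounding to the third decimal fixes the number of distinct representable
#' score values, so the fixed evaluation grid of [thresholdGrid()] is an
#' exhaustive threshold scan. Idempotent.
#'
#' @param pset a [PredictionSet-class].
#' @return the set with rounded scores.
#' @export
roundScores <- function(pset) {
  stopifnot(is(pset, "PredictionSet"))
  pset@scores <- IRanges::NumericList(lapply(pset@scores, roundHalfUp))
  pset
}

#' Resolve the effective decision threshold of a prediction set
#'
#' Threshold precedence: when states are present, the threshold is the
#' minimum score among state-positive residues across the whole set (and
#' the consistency of states with the `score >= threshold` rule is
#' checked; inconsistencies are counted, reported as an attribute and via
#' a warning, never silently ignored). Otherwise the author-declared
#' threshold is used if present, and 0.5 as the final default. Entries
#' without states receive states derived from scores at the resolved
#' threshold.
#'
#' @param pset a [PredictionSet-class]; scores should be rounded first
#'   (done internally if not).
#' @return the set with `effectiveThreshold` set and complete states; the
#'   number of state/threshold disagreements is attached as attribute
#'   `"inconsistencies"`.
#' @export
resolveThreshold <- function(pset) {
  stopifnot(is(pset, "PredictionSet"))
  pset <- roundScores(pset)
  inconsistencies <- 0L
  if (length(pset@states) > 0L) {
    sc <- unlist(pset@scores, use.names = FALSE)
    st <- unlist(pset@states, use.names = FALSE)
    if (any(st == 1L)) {
      thr <- min(sc[st == 1L])
      inconsistencies <- sum(.classify(sc, thr) != (st == 1L))
      if (inconsistencies > 0L)
        .warnf("method %s: %d state(s) inconsistent with inferred threshold %.3f",
               pset@methodName, inconsistencies, thr)
    } else {
      thr <- if (!is.na(pset@declaredThreshold)) pset@declaredThreshold else 0.5
      .warnf("method %s: states carry no positives; falling back to threshold %.3f",
             pset@methodName, thr)
    }
  } else {
    thr <- if (!is.na(pset@declaredThreshold)) pset@declaredThreshold else 0.5
    pset@states <- IRanges::IntegerList(
      lapply(pset@scores, function(x) as.integer(.classify(x, thr))))
  }
  pset@effectiveThreshold <- thr
  attr(pset, "inconsistencies") <- inconsistencies
  pset
}

#' Align a prediction set with a reference set
#'
#' Checks that every reference target has a prediction of matching length.
#' Missing targets are a hard error by default; with `allowMissing = TRUE`
#' the affected targets are dropped from evaluation with a warning.
#'
#' @param pset a [PredictionSet-class].
#' @param ref a [ReferenceSet-class].
#' @param allowMissing drop reference targets without predictions instead
#'   of erroring.
#' @return list with the aligned `pset` and `ref`.
#' @export
alignPrediction <- function(pset, ref, allowMissing = FALSE) {
  stopifnot(is(pset, "PredictionSet"), is(ref, "ReferenceSet"))
  missing <- setdiff(names(ref@labels), names(pset@scores))
  if (length(missing)) {
    if (!allowMissing)
      .stopf("method %s: no prediction for target(s): %s", pset@methodName,
             paste(missing, collapse = ", "))
    .warnf("method %s: dropping %d target(s) without predictions",
           pset@methodName, length(missing))
    ref <- subsetReference(ref, setdiff(names(ref@labels), missing))
  }
  keep <- names(ref@labels)
  pset@scores <- pset@scores[keep]
  if (length(pset@states)) pset@states <- pset@states[keep]
  lenMismatch <- lengths(pset@scores) != lengths(ref@labels)
  if (any(lenMismatch))
    .stopf("length mismatch between prediction and reference for target(s): %s",
           paste(keep[lenMismatch], collapse = ", "))
  list(pset = pset, ref = ref)
}
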