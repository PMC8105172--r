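.AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' BLOSUM62 background amino-acid frequencies
#'
#' The marginal amino-acid frequencies of the BLOSUM62 alignment blocks,
#' in fixed alphabetical one-letter order, renormalized to sum exactly
#' to 1. Used as the background distribution of the conservation baseline.
#'
#' @return named numeric vector of 20 frequencies.
#' @export
blosum62Background <- function() {
  path <- system.file("extdata", "blosum62_background.tsv",
                      package = "DisorderBench", mustWork = TRUE)
  tab <- utils::read.delim(path)
  f <- stats::setNames(tab$frequency, tab$aa)[.AA_ORDER]
  f / sum(f)
}

#' Jensen-Shannon divergence (base 2)
#'
#' `JSD(p, q) = H((p + q) / 2) - (H(p) + H(q)) / 2` with base-2 entropy
#' and the convention `0 * log(0) = 0`; bounded in \[0, 1\].
#'
#' @param p,q probability vectors of equal length (each summing to 1).
#' @return divergence in \[0, 1\].
#' @export
jsDivergence <- function(p, q) {
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  m <- (p + q) / 2
  v <- h(m) - (h(p) + h(q)) / 2
  min(1, max(0, v))
}

#' Random baseline predictor
#'
#' Assigns each residue an i.i.d. uniform \[0, 1\] score (rounded to three
#' decimals) with a decision threshold of 0.5.
#'
#' @param targets named [Biostrings::AAStringSet] or named length vector.
#' @param seed integer seed.
#' @param methodName report label.
#' @return a resolved [PredictionSet-class].
#' @export
randomBaseline <- function(targets, seed = 1L, methodName = "Random") {
  lens <- .targetLengths(targets)
  set.seed(seed)
  scores <- lapply(lens, function(L) roundHalfUp(stats::runif(L)))
  names(scores) <- names(lens)
  resolveThreshold(newPredictionSet(methodName, scores,
                                    declaredThreshold = 0.5))
}

#' Shuffled-dataset baseline predictor
#'
#' Randomly permutes the reference labels across the entire dataset: the
#' pool of unmasked positive/negative labels is permuted globally and the
#' permuted binary labels become the scores. This preserves the dataset
#' proportion of positive labels exactly, but not necessarily that of any
#' single target. Masked positions receive score 0 (inert, since masked
#' residues are excluded from every metric).
#'
#' @param ref a [ReferenceSet-class].
#' @inheritParams randomBaseline
#' @return a resolved [PredictionSet-class].
#' @export
shuffledBaseline <- function(ref, seed = 1L, methodName = "Shuffled") {
  stopifnot(is(ref, "ReferenceSet"))
  labs <- as.list(ref@labels)
  flat <- unlist(labs, use.names = FALSE)
  pool <- flat[!is.na(flat)]
  set.seed(seed)
  pool <- sample(pool)
  flat[!is.na(flat)] <- pool
  flat[is.na(flat)] <- 0L
  idx <- c(0L, cumsum(lengths(labs)))
  scores <- lapply(seq_along(labs), function(i)
    as.numeric(flat[(idx[i] + 1L):idx[i + 1L]]))
  states <- lapply(scores, as.integer)
  names(scores) <- names(states) <- names(labs)
  resolveThreshold(newPredictionSet(methodName, scores, states,
                                    declaredThreshold = 0.5))
}

#' Conservation baseline predictor (Jensen-Shannon divergence)
#'
#' Scores each residue by the base-2 Jensen-Shannon divergence between the
#' position's amino-acid frequency profile (from homologous sequences,
#' e.g. a PSSM-derived profile) and the BLOSUM62 background frequencies.
#' Scores lie in \[0, 1\]; a position with score strictly greater than 0.4
#' is classified as positive (disordered). An inversion flag is provided
#' (`invert = TRUE` emits `1 - JSD`) for the opposite reading where low
#' conservation signals disorder; the literal high-divergence rule is the
#' default.
#'
#' @param profiles named list of per-target profile matrices (rows =
#'   positions, 20 columns in the fixed alphabetical amino-acid order,
#'   each row summing to 1 within 1e-6), as from [readProfiles()] or
#'   [generateProfiles()].
#' @param background background frequencies (defaults to
#'   [blosum62Background()]).
#' @param invert emit `1 - JSD` instead of `JSD`.
#' @param methodName report label.
#' @return a resolved [PredictionSet-class] with declared threshold 0.4.
#' @export
conservationBaseline <- function(profiles, background = blosum62Background(),
                                 invert = FALSE,
                                 methodName = "Conservation") {
  stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-6)
  scores <- lapply(names(profiles), function(tid) {
    pm <- profiles[[tid]]
    if (ncol(pm) != 20L)
      .stopf("profile for target %s must have 20 columns", tid)
    rs <- rowSums(pm)
    if (any(abs(rs - 1) > 1e-6))
      .stopf("profile row(s) not summing to 1 for target %s (first at position %d)",
             tid, which(abs(rs - 1) > 1e-6)[1L])
    v <- vapply(seq_len(nrow(pm)), function(i)
      jsDivergence(pm[i, ], background), numeric(1))
    if (invert) v <- 1 - v
    roundHalfUp(v)
  })
  names(scores) <- names(profiles)
  # strict > 0.4 rule; on the 3-decimal grid this equals >= 0.401, so the
  # inferred min-positive-score threshold reproduces the states exactly
  states <- lapply(scores, function(x) as.integer(x > 0.4))
  resolveThreshold(newPredictionSet(methodName, scores, states,
                                    declaredThreshold = 0.4))
}

#' Structure-complement baseline predictor
#'
#' Implements the naive rule that whatever is not annotated as structure
#' is disordered: residues outside every structure-coverage interval score
#' 1.0, covered residues score 0.0, with threshold 0.5. A target with no
#' coverage record at all is scored all-1.0, i.e. classified fully
#' disordered whenever no structure is available. The same machinery
#' serves the observed-structure, close-homolog, remote-homolog and
#' domain-prediction variants, which differ only in the provenance of
#' their input coverage.
#'
#' @param coverage `GRanges` of structure-observed intervals (any `class`
#'   metadata is ignored; all intervals count as coverage).
#' @param targets named [Biostrings::AAStringSet] or named length vector.
#' @param methodName report label (e.g. "PDB-Observed", "PDB-Close").
#' @return a resolved [PredictionSet-class].
#' @export
structureComplementBaseline <- function(coverage, targets,
                                        methodName = "PDB-Observed") {
  lens <- .targetLengths(targets)
  scores <- lapply(names(lens), function(tid) {
    len <- lens[[tid]]
    covered <- logical(len)
    sel <- coverage[GenomicRanges::seqnames(coverage) == tid]
    for (i in seq_along(sel)) {
      s <- max(1L, GenomicRanges::start(sel)[i])
      e <- min(len, GenomicRanges::end(sel)[i])
      if (s <= e) covered[s:e] <- TRUE
    }
    as.numeric(!covered)
  })
  names(scores) <- names(lens)
  resolveThreshold(newPredictionSet(methodName, scores,
                                    declaredThreshold = 0.5))
}

#' Write / read per-position frequency profiles
#'
#' One tab-separated file per target under `dir`, named
#' `<target_id>.profile.tsv`: a header row `pos` plus the 20 amino-acid
#' letters in fixed alphabetical order, then one row per position with the
#' position index and 20 frequencies.
#'
#' @param profiles named list of profile matrices.
#' @param dir output directory (created if needed).
#' @return `writeProfiles` returns the file paths invisibly;
#'   `readProfiles` returns a named list of matrices.
#' @export
writeProfiles <- function(profiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(profiles), function(tid) {
    path <- file.path(dir, paste0(tid, ".profile.tsv"))
    pm <- profiles[[tid]]
    colnames(pm) <- .AA_ORDER
    df <- data.frame(pos = seq_len(nrow(pm)), pm, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(dir) {
  files <- list.files(dir, pattern = "\\.profile\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) .stopf("no .profile.tsv files under %s", dir)
  profiles <- lapply(files, function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    if (!identical(names(df)[1L], "pos") ||
        !identical(names(df)[-1L], .AA_ORDER))
      .stopf("%s: header must be 'pos' plus the 20 amino acids in alphabetical order",
             path)
    pm <- as.matrix(df[, .AA_ORDER])
    if (!identical(as.integer(df$pos), seq_len(nrow(pm))))
      .stopf("%s: positions must be consecutive from 1", path)
    rs <- rowSums(pm)
    if (any(abs(rs - 1) > 1e-6))
      .stopf("%s: profile row %d does not sum to 1", path,
             which(abs(rs - 1) > 1e-6)[1L])
    pm
  })
  names(profiles) <- sub("\\.profile\\.tsv$", "", basename(files))
  profiles
}
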