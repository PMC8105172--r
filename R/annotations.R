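#' Read target sequences from a FASTA file
#'
#' Targets are identified by the first whitespace-delimited word of each
#' FASTA header. Any uppercase letter is accepted in the sequence
#' (including X, B, Z); labels are alphabet-agnostic.
#'
#' @param path FASTA file.
#' @return [Biostrings::AAStringSet] named by target identifier.
#' @export
readTargets <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    .stopf("duplicate FASTA id(s): %s",
           paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

.targetLengths <- function(targets) {
  if (is(targets, "XStringSet")) {
    stats::setNames(Biostrings::width(targets), names(targets))
  } else if (is.numeric(targets) && !is.null(names(targets))) {
    targets
  } else .stopf("targets must be a named AAStringSet or named length vector")
}

#' Build canonical interval annotations from a table
#'
#' Validates interval records against the target sequences and returns a
#' canonical [GenomicRanges::GRanges]: per target and annotation class,
#' intervals are sorted and overlapping or adjacent intervals merged,
#' without changing residue membership. Coordinates are 1-based inclusive
#' throughout.
#'
#' @param df data.frame with columns `target_id`, `class`
#'   (one of `disorder`, `binding`, `structure_observed`), `start`, `end`.
#' @param targets named [Biostrings::AAStringSet] (or named length vector).
#' @return `GRanges` with a `class` metadata column; seqinfo carries target
#'   lengths.
#' @export
makeAnnotations <- function(df, targets) {
  lens <- .targetLengths(targets)
  need <- c("target_id", "class", "start", "end")
  if (!all(need %in% names(df)))
    .stopf("annotation table needs columns %s", paste(need, collapse = ", "))
  df$target_id <- as.character(df$target_id)
  df$class <- as.character(df$class)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df)) {
    bad <- !df$class %in% .ANNOTATION_CLASSES
    if (any(bad))
      .stopf("unknown annotation class(es): %s",
             paste(unique(df$class[bad]), collapse = ", "))
    unknown <- setdiff(df$target_id, names(lens))
    if (length(unknown))
      .stopf("annotation references unknown target(s): %s",
             paste(unknown, collapse = ", "))
    if (any(df$start > df$end) || any(df$start < 1L))
      .stopf("invalid interval: start must satisfy 1 <= start <= end")
    over <- df$end > lens[df$target_id]
    if (any(over)) {
      i <- which(over)[1L]
      .stopf("interval (%d,%d) on target %s: end %d > length %d",
             df$start[i], df$end[i], df$target_id[i], df$end[i],
             lens[df$target_id[i]])
    }
  }
  si <- GenomeInfoDb::Seqinfo(seqnames = names(lens),
                              seqlengths = unname(lens))
  if (nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = si)
    S4Vectors::mcols(gr)$class <- character()
    return(gr)
  }
  out <- lapply(.ANNOTATION_CLASSES, function(cl) {
    sub <- df[df$class == cl, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    gr <- GenomicRanges::GRanges(sub$target_id,
                                 IRanges::IRanges(sub$start, sub$end),
                                 seqinfo = si)
    gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
    S4Vectors::mcols(gr)$class <- cl
    gr
  })
  do.call(c, out[!vapply(out, is.null, logical(1))])
}

#' Read an interval annotation table
#'
#' Tab-separated columns `target_id`, `class`, `start`, `end`, one interval
#' per line; a header line is optional and `#` comment lines are ignored.
#'
#' @param path annotation file.
#' @inheritParams makeAnnotations
#' @return canonical `GRanges`, see [makeAnnotations()].
#' @export
readAnnotations <- function(path, targets) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) && grepl("^target_id\\b", lines[1L]))
    lines <- lines[-1L]
  if (length(lines) == 0L)
    return(makeAnnotations(
      data.frame(target_id = character(), class = character(),
                 start = integer(), end = integer()), targets))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L))
    .stopf("malformed annotation line (need 4 tab-separated fields): '%s'",
           lines[which(lengths(parts) < 4L)[1L]])
  m <- do.call(rbind, lapply(parts, `[`, 1:4))
  makeAnnotations(
    data.frame(target_id = m[, 1L], class = m[, 2L],
               start = as.integer(m[, 3L]), end = as.integer(m[, 4L])),
    targets)
}

.residueMask <- function(gr, target, cl, len) {
  mask <- logical(len)
  sel <- gr[GenomicRanges::seqnames(gr) == target &
              S4Vectors::mcols(gr)$class == cl]
  for (i in seq_along(sel))
    mask[GenomicRanges::start(sel)[i]:GenomicRanges::end(sel)[i]] <- TRUE
  mask
}

#' Build a residue-level reference set
#'
#' Applies the labelling rules of the three reference modes:
#' \describe{
#'   \item{disprot}{positives are disorder residues; all other residues are
#'     negative.}
#'   \item{disprot_pdb}{positives are disorder residues — disorder always
#'     overwrites structure; negatives are structure-observed residues not
#'     annotated as disordered; residues covered by neither annotation are
#'     masked and excluded from all metrics.}
#'   \item{binding}{positives are binding residues; all other residues are
#'     negative. Targets with no binding annotation are retained as
#'     all-negative entries.}
#' }
#' Targets present in `targets` but with no annotation of any class are
#' retained (all-negative in disprot/binding modes, all-masked in
#' disprot_pdb mode).
#'
#' @param targets named [Biostrings::AAStringSet] (or named length vector).
#' @param annotations canonical `GRanges` from [makeAnnotations()] /
#'   [readAnnotations()].
#' @param mode `"disprot"`, `"disprot_pdb"` or `"binding"`.
#' @return a [ReferenceSet-class] object.
#' @export
#' @examples
#' tg <- c(T1 = 10)
#' ann <- makeAnnotations(
#'   data.frame(target_id = "T1", class = c("disorder", "structure_observed"),
#'              start = c(1, 6), end = c(4, 8)), tg)
#' referenceLabels(buildReference(tg, ann, "disprot_pdb"))[["T1"]]
buildReference <- function(targets, annotations,
                           mode = c("disprot", "disprot_pdb", "binding")) {
  mode <- match.arg(mode)
  lens <- .targetLengths(targets)
  unknown <- setdiff(
    as.character(unique(GenomicRanges::seqnames(annotations))), names(lens))
  if (length(unknown))
    .stopf("annotation references target(s) absent from target list: %s",
           paste(unknown, collapse = ", "))
  labs <- lapply(names(lens), function(tid) {
    len <- lens[[tid]]
    dis <- .residueMask(annotations, tid, "disorder", len)
    switch(mode,
      disprot = as.integer(dis),
      binding = as.integer(.residueMask(annotations, tid, "binding", len)),
      disprot_pdb = {
        str <- .residueMask(annotations, tid, "structure_observed", len)
        out <- rep(NA_integer_, len)
        out[str] <- 0L      # structure-observed -> negative ...
        out[dis] <- 1L      # ... unless disordered: disorder overwrites
        out
      })
  })
  names(labs) <- names(lens)
  new("ReferenceSet", mode = mode, labels = IRanges::IntegerList(labs),
      provenance = sprintf("buildReference(mode=%s, %d targets, %s)",
                           mode, length(lens), format(Sys.time(), "%Y-%m-%d")))
}

#' Residue-class composition of a reference set
#'
#' @param ref a [ReferenceSet-class].
#' @return list with total `positives`, `negatives`, `masked`, `total`
#'   residue counts and a `perTarget` data.frame (per-target counts and
#'   annotation presence).
#' @export
referenceComposition <- function(ref) {
  stopifnot(is(ref, "ReferenceSet"))
  labs <- ref@labels
  pos <- vapply(labs, function(x) sum(x == 1L, na.rm = TRUE), integer(1))
  neg <- vapply(labs, function(x) sum(x == 0L, na.rm = TRUE), integer(1))
  msk <- vapply(labs, function(x) sum(is.na(x)), integer(1))
  list(positives = sum(pos), negatives = sum(neg), masked = sum(msk),
       total = sum(lengths(labs)),
       perTarget = data.frame(target_id = names(labs),
                              length = unname(lengths(labs)),
                              positives = unname(pos),
                              negatives = unname(neg),
                              masked = unname(msk),
                              has_positive = unname(pos > 0L),
                              row.names = NULL))
}

#' Write / read a reference set as line-oriented text
#'
#' Format: a `>` header with the target identifier, then one line with one
#' character per residue: `1` positive, `0` negative, `-` masked.
#'
#' @param ref a [ReferenceSet-class].
#' @param path output file.
#' @return `writeReferenceSet` returns `path` invisibly; `readReferenceSet`
#'   returns a [ReferenceSet-class].
#' @export
writeReferenceSet <- function(ref, path) {
  stopifnot(is(ref, "ReferenceSet"))
  enc <- vapply(ref@labels, function(x) {
    ch <- ifelse(is.na(x), "-", as.character(x))
    paste(ch, collapse = "")
  }, character(1))
  writeLines(c(sprintf("#mode\t%s", ref@mode),
               as.vector(rbind(paste0(">", names(enc)), enc))), path)
  invisible(path)
}

#' @rdname writeReferenceSet
#' @param mode reference mode override; by default read from the file's
#'   `#mode` comment.
#' @export
readReferenceSet <- function(path, mode = NULL) {
  lines <- readLines(path)
  if (is.null(mode)) {
    m <- grep("^#mode\t", lines, value = TRUE)
    mode <- if (length(m)) sub("^#mode\t", "", m[1L]) else "disprot"
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) .stopf("no reference entries in %s", path)
  labs <- lapply(seq_along(hdr), function(i) {
    body <- lines[hdr[i] + 1L]
    ch <- strsplit(body, "")[[1L]]
    bad <- !ch %in% c("0", "1", "-")
    if (any(bad)) .stopf("invalid label character '%s' in %s",
                         ch[bad][1L], lines[hdr[i]])
    out <- rep(NA_integer_, length(ch))
    out[ch == "1"] <- 1L
    out[ch == "0"] <- 0L
    out
  })
  names(labs) <- sub("^>", "", lines[hdr])
  new("ReferenceSet", mode = mode, labels = IRanges::IntegerList(labs),
      provenance = sprintf("readReferenceSet(%s)", path))
}

#' Restrict a reference set to a subset of targets
#'
#' @param ref a [ReferenceSet-class].
#' @param ids target identifiers to keep.
#' @return a [ReferenceSet-class] restricted to `ids`.
#' @export
subsetReference <- function(ref, ids) {
  stopifnot(is(ref, "ReferenceSet"))
  missing <- setdiff(ids, names(ref@labels))
  if (length(missing))
    .stopf("subset id(s) absent from reference: %s",
           paste(missing, collapse = ", "))
  if (length(ids) == 0L) .stopf("empty target subset")
  new("ReferenceSet", mode = ref@mode, labels = ref@labels[ids],
      provenance = paste0(ref@provenance, sprintf(" | subset(%d)",
                                                  length(ids))))
}
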