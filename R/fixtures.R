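#' Specification of a synthetic assessment dataset
#'
#' Defines the composition of a fully synthetic benchmark: target count,
#' sequence-length distribution, disorder-interval density, structure
#' coverage of the ordered complement, binding annotation frequency and
#' the fraction of fully disordered targets. Defaults mirror a curated
#' disorder benchmark of 646 targets in which 40 targets are at least 95%
#' disordered, 232 of 646 targets carry a binding annotation, disordered
#' regions are at least ten residues long, and binding regions always lie
#' inside disordered regions.
#'
#' @param nTargets number of target proteins.
#' @param lengthMeanLog,lengthSdLog log-normal sequence-length parameters.
#' @param minLength,maxLength hard bounds on sequence length.
#' @param disorderDensity expected fraction of disordered residues in a
#'   non-IDP target (capped at 0.9 so non-IDP targets stay below the IDP
#'   threshold).
#' @param minIntervalLength minimum disordered interval length (default
#'   10 residues).
#' @param structureCoverage fraction of each ordered segment covered by a
#'   structure-observed interval.
#' @param structureOverlap probability that a structure interval extends a
#'   few residues into adjacent disorder (exercises the
#'   disorder-overwrites-structure precedence).
#' @param bindingTargetFraction fraction of targets receiving a binding
#'   region (placed inside a disordered region).
#' @param idpFraction fraction of targets generated fully disordered
#'   (>= 95% disordered residues).
#' @param seed integer seed; the full fixture is reproducible from it.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(nTargets = 646L,
                        lengthMeanLog = log(300), lengthSdLog = 0.6,
                        minLength = 30L, maxLength = 2000L,
                        disorderDensity = 0.25, minIntervalLength = 10L,
                        structureCoverage = 0.6, structureOverlap = 0.15,
                        bindingTargetFraction = 232 / 646,
                        idpFraction = 40 / 646,
                        seed = 1L) {
  stopifnot(nTargets >= 1L, minIntervalLength >= 1L,
            disorderDensity >= 0, disorderDensity <= 0.9,
            structureCoverage >= 0, structureCoverage <= 1,
            bindingTargetFraction >= 0, bindingTargetFraction <= 1,
            idpFraction >= 0, idpFraction <= 1,
            minLength >= 2L * minIntervalLength)
  structure(list(nTargets = as.integer(nTargets),
                 lengthMeanLog = lengthMeanLog, lengthSdLog = lengthSdLog,
                 minLength = as.integer(minLength),
                 maxLength = as.integer(maxLength),
                 disorderDensity = disorderDensity,
                 minIntervalLength = as.integer(minIntervalLength),
                 structureCoverage = structureCoverage,
                 structureOverlap = structureOverlap,
                 bindingTargetFraction = bindingTargetFraction,
                 idpFraction = idpFraction, seed = as.integer(seed)),
            class = "FixtureSpec")
}

# place k non-overlapping intervals of the given lengths by rejection
# sampling; hard attempt cap so infeasible densities error out rather than
# silently under-filling
.placeIntervals <- function(L, lens, maxAttempts = 1000L) {
  k <- length(lens)
  if (k == 0L) return(NULL)
  if (sum(lens) + (k - 1L) > L)
    .stopf("infeasible interval placement: %d residues of intervals on length %d",
           sum(lens), L)
  for (attempt in seq_len(maxAttempts)) {
    starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), integer(1))
    ends <- starts + lens - 1L
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    if (k == 1L || all(starts[-1L] > ends[-k] + 1L))
      return(cbind(start = starts, end = ends))
  }
  .stopf("interval placement failed after %d attempts (density too high)",
         maxAttempts)
}

#' Generate a complete synthetic assessment dataset
#'
#' Draws sequences, disorder/structure/binding interval annotations and
#' exact ground-truth bookkeeping from a [fixtureSpec()]. Binding regions
#' always lie inside disordered regions; fully disordered targets are
#' annotated disordered over their whole length; structure intervals cover
#' part of the ordered complement and may overlap disorder edges (the
#' precedence rule resolves those). The bookkeeping is recomputed from the
#' final annotations, so it always equals an independent recount.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `targets` ([Biostrings::AAStringSet]), `annotations`
#'   (canonical `GRanges`), `truth` (per-target composition data.frame,
#'   totals, IDP target set) and `spec`.
#' @export
generateDataset <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  n <- spec$nTargets
  ids <- sprintf("SYN%04d", seq_len(n))
  lens <- pmin(spec$maxLength,
               pmax(spec$minLength,
                    as.integer(round(stats::rlnorm(n, spec$lengthMeanLog,
                                                   spec$lengthSdLog)))))
  names(lens) <- ids
  nIdp <- round(spec$idpFraction * n)
  idpTargets <- if (nIdp > 0L) sort(sample(ids, nIdp)) else character()
  bg <- blosum62Background()
  seqs <- vapply(lens, function(L)
    paste(sample(names(bg), L, replace = TRUE, prob = bg), collapse = ""),
    character(1))
  rows <- list()
  disList <- list()
  for (tid in ids) {
    L <- lens[[tid]]
    if (tid %in% idpTargets) {
      dis <- cbind(start = 1L, end = L)
    } else {
      D <- round(spec$disorderDensity * L)
      if (D < spec$minIntervalLength) D <- spec$minIntervalLength
      D <- min(D, floor(0.9 * L))
      if (D < spec$minIntervalLength || spec$disorderDensity == 0) {
        dis <- NULL
      } else {
        k <- max(1L, min(floor(D / (3L * spec$minIntervalLength)),
                         1L + stats::rpois(1L, 1)))
        # random composition of D into k parts, each >= minIntervalLength
        slack <- D - k * spec$minIntervalLength
        extra <- if (k > 1L)
          as.vector(stats::rmultinom(1L, slack, rep(1 / k, k)))
        else slack
        dis <- .placeIntervals(L, spec$minIntervalLength + extra)
      }
    }
    if (!is.null(dis))
      rows[[length(rows) + 1L]] <-
        data.frame(target_id = tid, class = "disorder",
                   start = dis[, "start"], end = dis[, "end"])
    # structure intervals over the ordered complement
    disMask <- logical(L)
    if (!is.null(dis))
      for (i in seq_len(nrow(dis))) disMask[dis[i, 1L]:dis[i, 2L]] <- TRUE
    r <- rle(disMask)
    segEnd <- cumsum(r$lengths)
    segStart <- segEnd - r$lengths + 1L
    for (j in which(!r$values)) {
      segLen <- r$lengths[j]
      w <- round(spec$structureCoverage * segLen)
      if (w < 1L) next
      off <- sample.int(segLen - w + 1L, 1L)
      s <- segStart[j] + off - 1L
      e <- s + w - 1L
      if (stats::runif(1) < spec$structureOverlap) {
        s <- max(1L, s - sample.int(5L, 1L))
        e <- min(L, e + sample.int(5L, 1L))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(target_id = tid, class = "structure_observed",
                   start = s, end = e)
    }
    if (!is.null(dis)) disList[[tid]] <- dis
  }
  withDisorder <- names(disList)
  nBind <- min(length(withDisorder), round(spec$bindingTargetFraction * n))
  bindTargets <- if (nBind > 0L) sample(withDisorder, nBind) else character()
  # binding regions always inside a disordered region
  for (tid in bindTargets) {
    dis <- disList[[tid]]
    i <- sample.int(nrow(dis), 1L)
    iLen <- dis[i, 2L] - dis[i, 1L] + 1L
    bLen <- max(1L, round(stats::runif(1, 0.2, 0.8) * iLen))
    bStart <- dis[i, 1L] + sample.int(iLen - bLen + 1L, 1L) - 1L
    rows[[length(rows) + 1L]] <-
      data.frame(target_id = tid, class = "binding",
                 start = bStart, end = bStart + bLen - 1L)
  }
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(target_id = character(), class = character(),
                  start = integer(), end = integer())
  targets <- Biostrings::AAStringSet(seqs)
  names(targets) <- ids
  ann <- makeAnnotations(df, targets)
  # bookkeeping by independent recount of the canonical annotations
  perTarget <- do.call(rbind, lapply(ids, function(tid) {
    L <- lens[[tid]]
    d <- sum(.residueMask(ann, tid, "disorder", L))
    s <- sum(.residueMask(ann, tid, "structure_observed", L))
    b <- sum(.residueMask(ann, tid, "binding", L))
    data.frame(target_id = tid, length = L, disorder = d, structure = s,
               binding = b, disorder_fraction = d / L,
               is_idp = d / L >= 0.95)
  }))
  list(targets = targets, annotations = ann,
       truth = list(perTarget = perTarget,
                    totals = c(residues = sum(perTarget$length),
                               disorder = sum(perTarget$disorder),
                               structure = sum(perTarget$structure),
                               binding = sum(perTarget$binding)),
                    idpTargets = perTarget$target_id[perTarget$is_idp]),
       spec = spec)
}

#' Specification of a synthetic noisy predictor
#'
#' Scores at truly disordered residues are drawn from
#' `Beta(posShape1, posShape2)` and scores elsewhere from
#' `Beta(negShape1, negShape2)`, both supported on \[0, 1\]. The expected
#' AUC of such a predictor is `P(S+ > S-) + P(S+ = S-) / 2` after
#' three-decimal rounding and is computed exactly by [aucOracle()].
#'
#' @param posShape1,posShape2 Beta parameters of the positive class.
#' @param negShape1,negShape2 Beta parameters of the negative class.
#' @return a `NoisyPredictorSpec` list.
#' @export
noisyPredictorSpec <- function(posShape1 = 4, posShape2 = 2,
                               negShape1 = 2, negShape2 = 4) {
  stopifnot(posShape1 > 0, posShape2 > 0, negShape1 > 0, negShape2 > 0)
  structure(list(posShape1 = posShape1, posShape2 = posShape2,
                 negShape1 = negShape1, negShape2 = negShape2),
            class = "NoisyPredictorSpec")
}

#' Exact expected AUC of a noisy predictor specification
#'
#' Discretizes the two Beta score distributions onto the 1001 rounding
#' bins (the probability mass each bin receives under half-up rounding to
#' three decimals) and evaluates
#' `AUC = sum_b m_neg(b) * (sum_(b' > b) m_pos(b') + m_pos(b) / 2)`
#' exactly. This is the numerical-integration oracle against which
#' measured AUCs of generated predictions are compared.
#'
#' @param nspec a [noisyPredictorSpec()].
#' @return expected AUC in \[0, 1\].
#' @export
aucOracle <- function(nspec) {
  stopifnot(inherits(nspec, "NoisyPredictorSpec"))
  edges <- c(0, (seq_len(1000L) - 0.5) / 1000, 1)
  mass <- function(a, b) diff(stats::pbeta(edges, a, b))
  mp <- mass(nspec$posShape1, nspec$posShape2)
  mn <- mass(nspec$negShape1, nspec$negShape2)
  # P(pos bin > neg bin) + 0.5 P(equal)
  sum(mn * (rev(cumsum(rev(mp))) - mp)) + 0.5 * sum(mn * mp)
}

#' Generate predictions with tunable accuracy for a synthetic dataset
#'
#' @param dataset a [generateDataset()] result.
#' @param nspec a [noisyPredictorSpec()].
#' @param seed integer seed.
#' @param methodName report label.
#' @return a resolved [PredictionSet-class] (threshold 0.5).
#' @export
generatePredictions <- function(dataset, nspec = noisyPredictorSpec(),
                                seed = 1L, methodName = "NoisySynthetic") {
  stopifnot(inherits(nspec, "NoisyPredictorSpec"))
  set.seed(seed)
  lens <- .targetLengths(dataset$targets)
  scores <- lapply(names(lens), function(tid) {
    L <- lens[[tid]]
    dis <- .residueMask(dataset$annotations, tid, "disorder", L)
    x <- numeric(L)
    x[dis] <- stats::rbeta(sum(dis), nspec$posShape1, nspec$posShape2)
    x[!dis] <- stats::rbeta(sum(!dis), nspec$negShape1, nspec$negShape2)
    roundHalfUp(x)
  })
  names(scores) <- names(lens)
  resolveThreshold(newPredictionSet(methodName, scores,
                                    declaredThreshold = 0.5))
}

#' Generate frequency profiles with tunable conservation contrast
#'
#' Disordered positions receive a profile mixed away from the background
#' towards a point mass on the position's own residue with weight
#' `contrast`; ordered positions receive the background itself. At
#' contrast 0 every Jensen-Shannon score is ~0 and the conservation
#' baseline carries no signal (AUC ~0.5); at contrast 1 disordered
#' positions are point masses and their divergence from the background is
#' maximal.
#'
#' @param dataset a [generateDataset()] result.
#' @param contrast mixing weight in \[0, 1\] for disordered positions.
#' @param background background frequencies.
#' @return named list of per-target profile matrices.
#' @export
generateProfiles <- function(dataset, contrast = 0.8,
                             background = blosum62Background()) {
  stopifnot(contrast >= 0, contrast <= 1)
  lens <- .targetLengths(dataset$targets)
  profiles <- lapply(names(lens), function(tid) {
    L <- lens[[tid]]
    aa <- strsplit(as.character(dataset$targets[[tid]]), "")[[1L]]
    dis <- .residueMask(dataset$annotations, tid, "disorder", L)
    pm <- matrix(rep(background, each = L), nrow = L,
                 dimnames = list(NULL, .AA_ORDER))
    for (i in which(dis)) {
      delta <- stats::setNames(numeric(20L), .AA_ORDER)
      hit <- if (aa[i] %in% .AA_ORDER) aa[i] else "A"
      delta[hit] <- 1
      pm[i, ] <- (1 - contrast) * background + contrast * delta
    }
    pm
  })
  names(profiles) <- names(lens)
  profiles
}

#' Write a synthetic dataset to disk in the consumed formats
#'
#' Emits `targets.fasta`, `annotations.tsv` (interval table) and
#' `ground_truth.json` under `dir`; these parse back through
#' [readTargets()] and [readAnnotations()].
#'
#' @param dataset a [generateDataset()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeFixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "targets.fasta")
  Biostrings::writeXStringSet(dataset$targets, fasta)
  annPath <- file.path(dir, "annotations.tsv")
  ann <- dataset$annotations
  df <- data.frame(target_id = as.character(GenomicRanges::seqnames(ann)),
                   class = S4Vectors::mcols(ann)$class,
                   start = GenomicRanges::start(ann),
                   end = GenomicRanges::end(ann))
  utils::write.table(df, annPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truthPath <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(dataset$truth, truthPath, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(c(fasta = fasta, annotations = annPath, truth = truthPath))
}
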