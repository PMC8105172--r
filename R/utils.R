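#' Round half-up on the decimal representation
#'
#' Rounds towards the nearest multiple of `10^-digits`, with ties going
#' away from zero (half-up), as opposed to [base::round()]'s IEEE
#' round-half-even. Idempotent: applying it twice equals applying it once.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' roundHalfUp(c(0.12345, 0.9996, 0.0005), 3)
roundHalfUp <- function(x, digits = 3L) {
  p <- 10^digits
  # small epsilon absorbs binary representation error of decimal inputs
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# integer grid index (0..1000) of a score already rounded to 3 decimals
.milli <- function(x) as.integer(floor(x * 1000 + 0.5 + 1e-9))

# score >= threshold classification rule, robust to binary representation
.classify <- function(scores, threshold) scores >= threshold - 1e-9

#' Fixed evaluation threshold grid
#'
#' The grid of candidate decision thresholds used for precision-recall and
#' ROC curves: 0.000, 0.001, ..., 1.000. Scores are rounded to three
#' decimals before evaluation, so every distinct score value lies on the
#' grid and a grid scan is an exhaustive threshold scan.
#'
#' @return numeric vector of length 1001.
#' @export
thresholdGrid <- function() seq(0, 1000L) / 1000

# safe ratio with the zero-denominator convention (value 0)
.ratio0 <- function(num, den) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  out <- numeric(n)
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
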