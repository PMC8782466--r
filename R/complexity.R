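#' Complexity configuration
#'
#' Bundles the tunable parameters of the nonlinear complexity features:
#' sample entropy template length `m` (default 2) and tolerance fraction
#' `rFrac` (default 0.2, i.e. r = 0.2 * SD), and the symbolic-dynamics
#' alphabet size (default 6), word length (default 3) and outlier-clipping
#' half-width in SDs (default 3). At the defaults the symbolic pattern space
#' holds `6^3 = 216` possible words.
#'
#' @param m sample-entropy template length, >= 1.
#' @param rFrac tolerance as a fraction of the series SD, > 0.
#' @param nSymbols symbolic alphabet size, >= 2.
#' @param wordLength symbols per overlapping word, >= 1.
#' @param clipSd clipping half-width in SDs, > 0.
#' @return A list of class `"ComplexityConfig"`.
#' @examples
#' cfg <- complexityConfig()
#' patternSpaceSize(cfg)  # 216
#' @export
complexityConfig <- function(m = 2L, rFrac = 0.2, nSymbols = 6L,
                             wordLength = 3L, clipSd = 3) {
  stopifnot(m >= 1L, rFrac > 0, nSymbols >= 2L, wordLength >= 1L, clipSd > 0)
  structure(list(m = as.integer(m), rFrac = rFrac,
                 nSymbols = as.integer(nSymbols),
                 wordLength = as.integer(wordLength), clipSd = clipSd),
            class = "ComplexityConfig")
}

#' @rdname complexityConfig
#' @param cfg a `ComplexityConfig`.
#' @export
patternSpaceSize <- function(cfg = complexityConfig()) {
  as.integer(cfg$nSymbols^cfg$wordLength)
}

#' Sample entropy
#'
#' SampEn(m, r): the negative natural logarithm of the conditional
#' probability that two sequences matching pointwise for `m` samples within
#' tolerance `r` also match at the next sample. Matching uses the Chebyshev
#' (maximum) distance with `<= r`, self-matches are excluded, and both
#' template sets run over the first `n - m` positions (the Richman-Moorman
#' convention). The tolerance is `r = rFrac * SD(series)`, so the estimate is
#' invariant to positive affine transforms of the series.
#'
#' Degenerate inputs are flagged, never silently zero: a zero-SD series (r =
#' 0) and series with no length-m or length-(m+1) matches return `NaN` with a
#' `"reason"` attribute naming the vanished count.
#'
#' @param series an [ActivitySeries-class] (complete) or numeric vector,
#'   length > m + 1.
#' @param cfg a [complexityConfig()]; `m` and `rFrac` are used.
#' @return Sample entropy in nats (possibly `NaN`, flagged).
#' @examples
#' set.seed(1)
#' sampleEntropy(runif(200))
#' @export
sampleEntropy <- function(series, cfg = complexityConfig()) {
  x <- .seriesValues(series, "sample entropy")
  m <- cfg$m
  n <- length(x)
  if (n <= m + 1L) stop("sample entropy requires length > m + 1")
  s <- stats::sd(x)
  if (s == 0)
    return(structure(NaN, reason = "zero tolerance: series SD is 0"))
  r <- cfg$rFrac * s
  N <- n - m  # template count for both m and m+1
  A <- 0; B <- 0
  # unordered template pairs, vectorised over the index offset d
  for (d in seq_len(N - 1L)) {
    i <- seq_len(N - d)
    ok <- abs(x[i] - x[i + d]) <= r
    for (j in seq_len(m - 1L))
      ok <- ok & (abs(x[i + j] - x[i + d + j]) <= r)
    B <- B + sum(ok)
    A <- A + sum(ok & (abs(x[i + m] - x[i + d + m]) <= r))
  }
  if (B == 0)
    return(structure(NaN, reason = "no template matches of length m"))
  if (A == 0)
    return(structure(NaN, reason = "no template matches of length m + 1"))
  -log(A / B)
}

#' Symbolic-dynamics distinct pattern count
#'
#' Coarse-grains the series into an alphabet of `nSymbols` (default 6)
#' symbols and counts the distinct overlapping words of `wordLength`
#' (default 3) consecutive symbols. To blunt the effect of outliers, values
#' are first clipped to mean +/- `clipSd` SDs; the clipped range is then
#' split into `nSymbols` equal-width bins (left-closed, the top bin closed on
#' the right). A zero range after clipping maps every minute to symbol 1 and
#' returns a count of 1 (documented degenerate convention). The count is
#' invariant to positive affine transforms of the series.
#'
#' @param series an [ActivitySeries-class] (complete) or numeric vector,
#'   length >= `wordLength`.
#' @param cfg a [complexityConfig()]; `nSymbols`, `wordLength` and `clipSd`
#'   are used.
#' @return Integer count of distinct observed words, in
#'   `[1, nSymbols^wordLength]`.
#' @examples
#' symbolicDynamicsCount(rep(5, 10))  # 1
#' @export
symbolicDynamicsCount <- function(series, cfg = complexityConfig()) {
  x <- .seriesValues(series, "symbolic dynamics")
  w <- cfg$wordLength
  n <- length(x)
  if (n < w) stop("series shorter than the word length")
  mu <- mean(x)
  s <- stats::sd(x)
  xc <- pmin(pmax(x, mu - cfg$clipSd * s), mu + cfg$clipSd * s)
  lo <- min(xc); hi <- max(xc)
  if (hi == lo) {
    sym <- rep(1L, n)
  } else {
    width <- (hi - lo) / cfg$nSymbols
    sym <- pmin(cfg$nSymbols, as.integer(floor((xc - lo) / width)) + 1L)
  }
  # encode each overlapping word in base nSymbols
  nw <- n - w + 1L
  code <- numeric(nw)
  for (j in seq_len(w))
    code <- code * cfg$nSymbols + sym[seq.int(j, j + nw - 1L)]
  length(unique(code))
}
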