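#' @import methods
NULL

setOldClass("POSIXct")

#' Raw tri-axial accelerometer recording
#'
#' Container for a raw wrist-accelerometer signal: three acceleration axes in
#' gravitational-force equivalents (g) sampled at a fixed rate (32 Hz for the
#' Empatica E4 class of devices).
#'
#' @slot x,y,z numeric vectors of equal length, acceleration per axis in g.
#' @slot samplingRate samples per second (> 0).
#' @slot startTime POSIXct timestamp (UTC) of the first sample.
#'
#' @seealso [rawAccelSeries()], [minuteCounts()], [readRawAccel()]
#' @export
setClass("RawAccelSeries",
  representation(
    x = "numeric", y = "numeric", z = "numeric",
    samplingRate = "numeric", startTime = "POSIXct"
  )
)

setValidity("RawAccelSeries", function(object) {
  msg <- character()
  n <- length(object@x)
  if (length(object@y) != n || length(object@z) != n)
    msg <- c(msg, "x, y and z must have equal length")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  else if (n < object@samplingRate * 60)
    msg <- c(msg, "recording must span at least one full minute")
  if (length(msg)) msg else TRUE
})

#' Construct a RawAccelSeries
#'
#' @param x,y,z numeric acceleration vectors (g), equal length.
#' @param samplingRate samples per second, default 32.
#' @param startTime POSIXct start of recording (UTC).
#' @return A [RawAccelSeries-class] object.
#' @examples
#' raw <- rawAccelSeries(x = numeric(1920), y = numeric(1920),
#'                       z = rep(1, 1920), samplingRate = 32)
#' @export
rawAccelSeries <- function(x, y, z, samplingRate = 32,
                           startTime = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  new("RawAccelSeries", x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
      samplingRate = as.numeric(samplingRate), startTime = startTime)
}

.VALID_STATES <- c("manic", "euthymic", "unlabelled")

#' Per-minute activity-count series
#'
#' One activity count per minute (non-negative) with a missingness mask,
#' a start timestamp and subject/mood-state labels. This is the unit every
#' feature in the package is computed on.
#'
#' @slot counts numeric per-minute activity values; `NA` allowed only where
#'   the mask flags a minute as missing.
#' @slot missing logical mask, same length as `counts`.
#' @slot startTime POSIXct timestamp of the first minute.
#' @slot subjectId character scalar.
#' @slot state one of `"manic"`, `"euthymic"`, `"unlabelled"`.
#' @slot epochLabel free-text label of the analysed window (e.g. "full-1190").
#'
#' @seealso [activitySeries()], [imputeMissing()], [extractEpoch()]
#' @export
setClass("ActivitySeries",
  representation(
    counts = "numeric", missing = "logical", startTime = "POSIXct",
    subjectId = "character", state = "character", epochLabel = "character"
  )
)

setValidity("ActivitySeries", function(object) {
  msg <- character()
  if (length(object@missing) != length(object@counts))
    msg <- c(msg, "missing mask and counts must have equal length")
  else {
    obs <- object@counts[!object@missing]
    if (anyNA(obs))
      msg <- c(msg, "non-missing counts must not be NA")
    else if (any(obs < 0))
      msg <- c(msg, "activity counts must be non-negative")
  }
  if (length(object@state) != 1L || !object@state %in% .VALID_STATES)
    msg <- c(msg, sprintf("state must be one of %s",
                          paste(.VALID_STATES, collapse = ", ")))
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an ActivitySeries
#'
#' @param counts numeric per-minute activity counts.
#' @param missing logical mask; defaults to `is.na(counts)`.
#' @param startTime POSIXct timestamp of the first minute.
#' @param subjectId subject identifier.
#' @param state mood-state label: "manic", "euthymic" or "unlabelled".
#' @param epochLabel label of the window the series represents.
#' @return An [ActivitySeries-class] object.
#' @examples
#' s <- activitySeries(c(10, 12, NA, 9), subjectId = "S01")
#' missingMask(s)
#' @export
activitySeries <- function(counts, missing = is.na(counts),
                           startTime = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                           subjectId = "", state = "unlabelled",
                           epochLabel = "full") {
  new("ActivitySeries", counts = as.numeric(counts), missing = as.logical(missing),
      startTime = startTime, subjectId = as.character(subjectId),
      state = as.character(state), epochLabel = as.character(epochLabel))
}

#' Epoch specification
#'
#' A contiguous analysis window inside a recording: an offset (minutes from
#' the start), a duration and a label. The study-level defaults are the full
#' first 1190 minutes and two 120-minute windows (morning 08:00-10:00,
#' evening 20:00-22:00 clock time).
#'
#' @slot offset integer minutes from the start of the series, >= 0.
#' @slot duration integer window length in minutes, > 0.
#' @slot label free-text label.
#' @seealso [epochSpec()], [extractEpoch()]
#' @export
setClass("EpochSpec",
  representation(offset = "integer", duration = "integer", label = "character")
)

setValidity("EpochSpec", function(object) {
  msg <- character()
  if (length(object@offset) != 1L || is.na(object@offset) || object@offset < 0L)
    msg <- c(msg, "offset must be a single integer >= 0")
  if (length(object@duration) != 1L || is.na(object@duration) || object@duration <= 0L)
    msg <- c(msg, "duration must be a single integer > 0")
  if (length(msg)) msg else TRUE
}
)

#' Construct an EpochSpec
#'
#' @param offset minutes from the start of the series (integer >= 0).
#' @param duration window length in minutes (integer > 0).
#' @param label window label.
#' @return An [EpochSpec-class] object.
#' @examples
#' epochSpec(0, 1190, "full-1190")
#' @export
epochSpec <- function(offset, duration, label = sprintf("epoch-%d+%d", offset, duration)) {
  new("EpochSpec", offset = as.integer(offset), duration = as.integer(duration),
      label = as.character(label))
}

#' Similarity graph of an activity series
#'
#' Undirected graph over the time points of a series: node u carries weight
#' x_u, and nodes u, v are joined when they are close in time (|u - v|
#' compared against k) and similar in value
#' (max(x_u, x_v) / min(x_u, x_v) < ratio threshold).
#'
#' @slot n number of nodes (time points).
#' @slot weights node weights, the series values.
#' @slot k neighbourhood parameter.
#' @slot ratioThreshold similarity ratio threshold (default 1.2).
#' @slot comparator `"strict_less"` (`|u-v| < k`) or `"less_equal"`.
#' @slot zeroRule how zero-valued pairs are resolved:
#'   `"both_zero_similar"` or `"any_zero_dissimilar"`.
#' @slot edges two-column integer matrix of node pairs, u < v, no duplicates.
#' @seealso [buildSimilarityGraph()], [graphMetrics()]
#' @export
setClass("SimilarityGraph",
  representation(
    n = "integer", weights = "numeric", k = "integer",
    ratioThreshold = "numeric", comparator = "character",
    zeroRule = "character", edges = "matrix"
  )
)

setValidity("SimilarityGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (!is.integer(e) || ncol(e) != 2L)
    msg <- c(msg, "edges must be a two-column integer matrix")
  else if (nrow(e)) {
    if (any(e < 1L) || any(e > object@n))
      msg <- c(msg, "edge endpoints out of range")
    if (any(e[, 1L] >= e[, 2L]))
      msg <- c(msg, "edges must be stored with u < v (no self-loops)")
    if (anyDuplicated(e))
      msg <- c(msg, "duplicate edges")
    d <- e[, 2L] - e[, 1L]
    ok <- if (object@comparator == "strict_less") all(d < object@k) else all(d <= object@k)
    if (!ok) msg <- c(msg, "an edge violates the distance criterion")
  }
  if (length(object@weights) != object@n)
    msg <- c(msg, "weights must have length n")
  if (!object@comparator %in% c("strict_less", "less_equal"))
    msg <- c(msg, "unknown comparator")
  if (!object@zeroRule %in% c("both_zero_similar", "any_zero_dissimilar"))
    msg <- c(msg, "unknown zeroRule")
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (object@ratioThreshold <= 1) msg <- c(msg, "ratioThreshold must be > 1")
  if (length(msg)) msg else TRUE
})
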