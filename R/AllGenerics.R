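#' Accessors for actimood classes
#'
#' Small accessor generics: `counts()` returns the per-minute values,
#' `missingMask()` the logical missingness mask, `startTime()` the first
#' timestamp, `subjectId()` / `moodState()` / `epochLabel()` the labels,
#' `nMinutes()` the series length, `edgeMatrix()` the edge list of a
#' similarity graph and `nodeWeights()` its node weights.
#'
#' @param object an actimood S4 object.
#' @return The corresponding slot value.
#' @name accessors
#' @examples
#' s <- activitySeries(c(1, 2, 3))
#' counts(s); nMinutes(s)
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("moodState", function(object) standardGeneric("moodState"))
#' @rdname accessors
#' @export
setGeneric("epochLabel", function(object) standardGeneric("epochLabel"))
#' @rdname accessors
#' @export
setGeneric("nMinutes", function(object) standardGeneric("nMinutes"))
#' @rdname accessors
#' @export
setGeneric("edgeMatrix", function(object) standardGeneric("edgeMatrix"))
#' @rdname accessors
#' @export
setGeneric("nodeWeights", function(object) standardGeneric("nodeWeights"))

#' @rdname accessors
#' @export
setMethod("counts", "ActivitySeries", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("missingMask", "ActivitySeries", function(object) object@missing)
#' @rdname accessors
#' @export
setMethod("startTime", "ActivitySeries", function(object) object@startTime)
#' @rdname accessors
#' @export
setMethod("startTime", "RawAccelSeries", function(object) object@startTime)
#' @rdname accessors
#' @export
setMethod("subjectId", "ActivitySeries", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("moodState", "ActivitySeries", function(object) object@state)
#' @rdname accessors
#' @export
setMethod("epochLabel", "ActivitySeries", function(object) object@epochLabel)
#' @rdname accessors
#' @export
setMethod("nMinutes", "ActivitySeries", function(object) length(object@counts))
#' @rdname accessors
#' @export
setMethod("edgeMatrix", "SimilarityGraph", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("nodeWeights", "SimilarityGraph", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "RawAccelSeries", function(object) object@samplingRate)

setMethod("show", "RawAccelSeries", function(object) {
  cat(sprintf("RawAccelSeries: %d samples at %g Hz (%.1f min), start %s\n",
              length(object@x), object@samplingRate,
              length(object@x) / (object@samplingRate * 60),
              format(object@startTime, "%Y-%m-%d %H:%M", tz = "UTC")))
})

setMethod("show", "ActivitySeries", function(object) {
  n <- length(object@counts)
  cat(sprintf("ActivitySeries '%s' [%s, %s]: %d minutes, %d missing, start %s\n",
              object@subjectId, object@state, object@epochLabel,
              n, sum(object@missing),
              format(object@startTime, "%Y-%m-%d %H:%M", tz = "UTC")))
  if (n) {
    obs <- object@counts[!object@missing]
    if (length(obs))
      cat(sprintf("  counts: mean %.2f, range [%.2f, %.2f]\n",
                  mean(obs), min(obs), max(obs)))
  }
})

setMethod("show", "EpochSpec", function(object) {
  cat(sprintf("EpochSpec '%s': offset %d min, duration %d min\n",
              object@label, object@offset, object@duration))
})

setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf(
    "SimilarityGraph: %d nodes, %d edges (k = %d, %s, ratio < %g)\n",
    object@n, nrow(object@edges), object@k,
    if (object@comparator == "strict_less") "|u-v| < k" else "|u-v| <= k",
    object@ratioThreshold))
})
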