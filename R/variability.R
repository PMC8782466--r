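# Accept either an ActivitySeries (must be complete) or a bare numeric vector.
.seriesValues <- function(series, what = "feature computation") {
  if (is(series, "ActivitySeries")) {
    if (any(series@missing))
      stop(what, " requires a complete series; impute missing minutes first")
    series@counts
  } else if (is.numeric(series)) {
    if (anyNA(series)) stop(what, " requires a complete series (NA found)")
    as.numeric(series)
  } else stop("expected an ActivitySeries or a numeric vector")
}

#' Linear variability features of an activity epoch
#'
#' Computes the five linear descriptors of a per-minute activity series:
#' \describe{
#'   \item{mean}{arithmetic mean of the counts.}
#'   \item{cv_percent}{coefficient of variation, 100 * SD / mean, with the
#'     sample (n-1) SD. Reported in place of the raw SD because activity
#'     series have unstable means.}
#'   \item{rmssd_percent}{root mean square of successive differences as a
#'     percentage of the mean: 100 * sqrt(sum(diff(x)^2) / (n-1)) / mean.}
#'   \item{rmssd_sd_ratio}{raw RMSSD / raw SD; indexes how much of the
#'     variability lives in minute-to-minute fluctuation.}
#'   \item{autocorr_lag1}{lag-1 autocorrelation,
#'     sum((x_t - xbar)(x_{t+1} - xbar)) / sum((x_t - xbar)^2).}
#' }
#' Undefined features (zero mean for the percentage features, zero SD for the
#' ratio and autocorrelation) are flagged as `NaN`, never silently zero.
#'
#' @param series an [ActivitySeries-class] with no missing minutes, or a
#'   numeric vector; length >= 3.
#' @return Named numeric vector with the five features above.
#' @examples
#' variabilityFeatures(c(1, 2, 3))
#' @export
variabilityFeatures <- function(series) {
  x <- .seriesValues(series, "variability")
  n <- length(x)
  if (n < 3L) stop("variability features require length >= 3")
  mu <- mean(x)
  s <- stats::sd(x)
  rmssd <- sqrt(sum(diff(x)^2) / (n - 1))
  cv <- if (mu == 0) NaN else 100 * s / mu
  rmssdPct <- if (mu == 0) NaN else 100 * rmssd / mu
  ratio <- if (s == 0) NaN else rmssd / s
  ac <- if (s == 0) NaN else {
    d <- x - mu
    sum(d[-n] * d[-1L]) / sum(d^2)
  }
  c(mean = mu, cv_percent = cv, rmssd_percent = rmssdPct,
    rmssd_sd_ratio = ratio, autocorr_lag1 = ac)
}
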