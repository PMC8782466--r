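# Fixed AR(1) coefficient of the log-noise process. The multiplicative noise
# is exp(AR(1) Gaussian), right-skewed with unit mean; the autocorrelation of
# the log-noise is what gives simulated minutes their short-range memory.
.NOISE_AR <- 0.7

# Recordings are assumed to start at this clock time (the study protocol
# started recordings around midday); epoch clock windows are resolved
# against it.
.SIM_START_CLOCK <- "13:00"

#' Simulation parameters for one synthetic recording
#'
#' The generator is phenomenological: a circadian (24 h) and an ultradian
#' (4 h) sinusoid around a baseline, gated by a low-activity sleep window,
#' multiplied by right-skewed unit-mean noise (exponentiated AR(1) Gaussian)
#' with sporadic burst/drop events. It emulates the per-minute, non-negative,
#' right-skewed activity counts the analysis assumes, not the physiology
#' behind them.
#'
#' @param minutes series length (default 1190, one full analysis epoch).
#' @param mesor baseline counts/min.
#' @param circadianAmplitude amplitude of the 24-h sinusoid (counts/min).
#' @param ultradianAmplitude amplitude of the 4-h sinusoid (counts/min).
#' @param sleepStart clock minute (0-1439) at which the sleep gate opens.
#' @param sleepDuration sleep gate length in minutes (< 1440).
#' @param sleepLevel activity during sleep as a fraction of the waking level.
#' @param noiseDispersion marginal SD of the log-noise (right-skew strength).
#' @param irregularity per-minute probability of an independent burst or drop
#'   event, in `[0, 1]`.
#' @return A list of class `"SimParams"`.
#' @seealso [euthymicPreset()], [manicPreset()], [simulateRecording()]
#' @export
simParams <- function(minutes = 1190, mesor = 300, circadianAmplitude = 200,
                      ultradianAmplitude = 60, sleepStart = 23 * 60,
                      sleepDuration = 450, sleepLevel = 0.05,
                      noiseDispersion = 0.35, irregularity = 0.01) {
  p <- list(minutes = as.integer(minutes), mesor = mesor,
            circadianAmplitude = circadianAmplitude,
            ultradianAmplitude = ultradianAmplitude,
            sleepStart = as.integer(sleepStart),
            sleepDuration = as.integer(sleepDuration),
            sleepLevel = sleepLevel, noiseDispersion = noiseDispersion,
            irregularity = irregularity)
  stopifnot(p$minutes >= 3L, p$mesor >= 0,
            p$circadianAmplitude >= 0, p$ultradianAmplitude >= 0,
            p$sleepStart >= 0L, p$sleepStart < 1440L,
            p$sleepDuration >= 0L, p$sleepDuration < 1440L,
            p$sleepLevel >= 0, p$sleepLevel <= 1,
            p$noiseDispersion >= 0,
            p$irregularity >= 0, p$irregularity <= 1)
  class(p) <- "SimParams"
  p
}

#' Mood-state presets for the synthetic cohort
#'
#' `euthymicPreset()` carries a pronounced circadian cycle, consolidated
#' sleep and moderate noise; `manicPreset()` attenuates the circadian
#' amplitude, fragments sleep (higher `sleepLevel`) and raises the noise
#' dispersion and burst rate. By construction the manic preset yields, in
#' expectation, lower CV%, higher sample entropy, fewer k = 2 edges, more
#' k = 5 bridges and fewer 3-cliques than the euthymic preset -- the
#' direction pattern of the published mania-vs-euthymia contrasts.
#'
#' @param minutes recording length; cohort recordings default to a nominal
#'   24-h recording so the morning clock window fits.
#' @return A `"SimParams"` list.
#' @export
euthymicPreset <- function(minutes = 1440) {
  simParams(minutes = minutes)
}

#' @rdname euthymicPreset
#' @export
manicPreset <- function(minutes = 1440) {
  simParams(minutes = minutes, circadianAmplitude = 60, sleepLevel = 0.45,
            noiseDispersion = 0.50, irregularity = 0.05)
}

# minutes-of-day for each simulated minute, given the fixed start clock
.clockMinutes <- function(n) {
  start <- as.integer(strsplit(.SIM_START_CLOCK, ":")[[1L]])
  (start[1L] * 60L + start[2L] + seq_len(n) - 1L) %% 1440L
}

#' Simulate one per-minute activity recording
#'
#' Draws `counts[t] = gate(t) * max(0, mesor + circadian + ultradian) *
#' noise(t)`, where the gate is `sleepLevel` inside the sleep clock window
#' and 1 outside, the noise is exponentiated AR(1) Gaussian scaled to unit
#' mean, and irregularity events multiply isolated minutes by a burst
#' (2-5x) or drop (0-0.2x) factor with equal probability. Counts are
#' non-negative by construction and the output is fully determined by
#' `seed`.
#'
#' @param params a [simParams()] list.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param subjectId,state labels attached to the series.
#' @return An [ActivitySeries-class] starting at 13:00 UTC.
#' @examples
#' s <- simulateRecording(euthymicPreset(), seed = 1)
#' @export
simulateRecording <- function(params, seed = NULL, subjectId = "sim",
                              state = "unlabelled") {
  stopifnot(inherits(params, "SimParams"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$minutes
  clock <- .clockMinutes(n)
  # circadian peak mid-afternoon (16:00), trough 04:00
  circ <- params$circadianAmplitude * cos(2 * pi * (clock - 960) / 1440)
  ultra <- params$ultradianAmplitude * sin(2 * pi * clock / 240)
  base <- pmax(0, params$mesor + circ + ultra)
  sleepEnd <- (params$sleepStart + params$sleepDuration) %% 1440L
  inSleep <- if (params$sleepStart + params$sleepDuration <= 1440L)
    clock >= params$sleepStart & clock < params$sleepStart + params$sleepDuration
  else
    clock >= params$sleepStart | clock < sleepEnd
  gate <- ifelse(inSleep, params$sleepLevel, 1)
  sig <- params$noiseDispersion
  if (sig > 0) {
    innov <- stats::rnorm(n, sd = sig * sqrt(1 - .NOISE_AR^2))
    g <- as.numeric(stats::filter(innov, .NOISE_AR, method = "recursive"))
    noise <- exp(g - sig^2 / 2)  # unit-mean lognormal, AR-correlated
  } else {
    noise <- rep(1, n)
  }
  cnt <- gate * base * noise
  if (params$irregularity > 0) {
    hit <- stats::runif(n) < params$irregularity
    if (any(hit)) {
      nh <- sum(hit)
      burst <- stats::runif(nh) < 0.5
      fac <- ifelse(burst, stats::runif(nh, 2, 5), stats::runif(nh, 0, 0.2))
      cnt[hit] <- cnt[hit] * fac
    }
  }
  start <- as.POSIXct(paste("2020-01-01", .SIM_START_CLOCK), tz = "UTC")
  activitySeries(cnt, missing = rep(FALSE, n), startTime = start,
                 subjectId = subjectId, state = state)
}

#' Simulate a paired manic/euthymic cohort
#'
#' Generates `nPairs` subjects, each with one recording per mood state.
#' Subject-level random effects (log-normal multipliers on the mesor and on
#' the circadian amplitude) are shared across the two states of a subject, so
#' the pairing carries real within-subject correlation. Deterministic in
#' `seed`.
#'
#' @param nPairs number of subjects, >= 2.
#' @param manic,euthymic `"SimParams"` presets for the two states.
#' @param seed integer seed.
#' @return A list with `recordings` (list of [ActivitySeries-class], 2 per
#'   subject) and `manifest` (data.frame: subject_id, state, index).
#' @examples
#' coh <- simulateCohort(3, seed = 1)
#' coh$manifest
#' @export
simulateCohort <- function(nPairs, manic = manicPreset(),
                           euthymic = euthymicPreset(), seed = NULL) {
  if (nPairs < 2L) stop("nPairs must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%02d", seq_len(nPairs))
  mesorMult <- exp(stats::rnorm(nPairs, sd = 0.15))
  amplMult <- exp(stats::rnorm(nPairs, sd = 0.20))
  recordings <- vector("list", 2L * nPairs)
  manifest <- data.frame(subject_id = rep(ids, each = 2L),
                         state = rep(c("manic", "euthymic"), nPairs),
                         index = seq_len(2L * nPairs),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nPairs)) {
    for (st in c("manic", "euthymic")) {
      p <- if (st == "manic") manic else euthymic
      p$mesor <- p$mesor * mesorMult[i]
      p$circadianAmplitude <- p$circadianAmplitude * amplMult[i]
      p$ultradianAmplitude <- p$ultradianAmplitude * amplMult[i]
      idx <- (i - 1L) * 2L + if (st == "manic") 1L else 2L
      recordings[[idx]] <- simulateRecording(p, seed = NULL,
                                             subjectId = ids[i], state = st)
    }
  }
  list(recordings = recordings, manifest = manifest)
}

#' Expand a per-minute series into synthetic raw 32 Hz acceleration
#'
#' Inverse of [minuteCounts()] up to noise: for each target minute with count
#' c, draws 1920 positive within-minute weights normalised to mean 1 and sets
#' the sample magnitudes to `1 + c * w`, so the per-minute mean of
#' `|magnitude - 1|` equals c up to floating-point error. Each sample's
#' magnitude is spread over the three axes by a random direction on the
#' sphere. A target of 0 yields samples of magnitude exactly 1 g (rest).
#'
#' @param target an [ActivitySeries-class] (complete) or numeric vector of
#'   per-minute counts, or a `"SimParams"` list (a recording is simulated
#'   first).
#' @param seed integer seed.
#' @param samplingRate samples/second (default 32).
#' @return A [RawAccelSeries-class].
#' @examples
#' raw <- simulateRaw(c(0.5, 1), seed = 1)
#' counts(minuteCounts(raw))
#' @export
simulateRaw <- function(target, seed = NULL, samplingRate = 32) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(target, "SimParams"))
    target <- simulateRecording(target, seed = NULL)
  cnt <- .seriesValues(target, "raw expansion")
  if (any(cnt < 0)) stop("target counts must be non-negative")
  start <- if (is(target, "ActivitySeries")) target@startTime
           else as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  spm <- as.integer(round(samplingRate * 60))
  nTot <- spm * length(cnt)
  w <- stats::runif(nTot, 0.5, 1.5)
  wm <- matrix(w, nrow = spm)
  wm <- sweep(wm, 2L, colMeans(wm), "/")  # exact unit mean per minute
  mag <- 1 + as.vector(wm) * rep(cnt, each = spm)
  theta <- acos(stats::runif(nTot, -1, 1))
  phi <- stats::runif(nTot, 0, 2 * pi)
  rawAccelSeries(mag * sin(theta) * cos(phi),
                 mag * sin(theta) * sin(phi),
                 mag * cos(theta),
                 samplingRate = samplingRate, startTime = start)
}
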