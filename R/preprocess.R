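#' Read a raw tri-axial accelerometer CSV
#'
#' Two dialects are supported. `empatica_header` follows the ACC.csv layout
#' of Empatica-style devices: line 1 carries the start UNIX timestamp
#' (repeated per column), line 2 the sampling rate per column, then one
#' `x,y,z` row per sample. `plain_xyz` is a bare three-column numeric file;
#' sampling rate and start time are supplied by the caller.
#'
#' @param path path to the CSV file.
#' @param dialect `"empatica_header"` or `"plain_xyz"`.
#' @param samplingRate samples/second, used for `plain_xyz` only.
#' @param startTime POSIXct start, used for `plain_xyz` only.
#' @return A [RawAccelSeries-class].
#' @seealso [writeRawAccel()], [minuteCounts()]
#' @export
readRawAccel <- function(path, dialect = c("empatica_header", "plain_xyz"),
                         samplingRate = 32,
                         startTime = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  skip <- 0L
  if (dialect == "empatica_header") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L) stop("empatica_header file must have two header lines")
    ts <- suppressWarnings(as.numeric(strsplit(hdr[1L], ",")[[1L]][1L]))
    rate <- suppressWarnings(as.numeric(strsplit(hdr[2L], ",")[[1L]][1L]))
    if (is.na(ts)) stop("malformed start timestamp on line 1 of ", path)
    if (is.na(rate) || rate <= 0) stop("malformed sampling rate on line 2 of ", path)
    startTime <- as.POSIXct(ts, origin = "1970-01-01", tz = "UTC")
    samplingRate <- rate
    skip <- 2L
  }
  dat <- tryCatch(
    utils::read.csv(path, header = FALSE, skip = skip,
                    colClasses = rep("numeric", 3L)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(dat) || ncol(dat) != 3L) {
    .rawParseError(path, skip)  # always stops, naming the offending line
  }
  rawAccelSeries(dat[[1L]], dat[[2L]], dat[[3L]],
                 samplingRate = samplingRate, startTime = startTime)
}

# Locate the first malformed data row and raise a parse error naming its
# 1-based line number in the file.
.rawParseError <- function(path, skip) {
  lines <- readLines(path)
  num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
  for (i in seq_along(lines)) {
    if (i <= skip) next
    fields <- trimws(strsplit(lines[i], ",")[[1L]])
    if (length(fields) != 3L || !all(grepl(num_re, fields)))
      stop(sprintf("parse error in %s at line %d: expected three numeric fields, got '%s'",
                   path, i, lines[i]))
  }
  stop("failed to parse ", path)
}

#' Write a raw accelerometer series to CSV
#'
#' Inverse of [readRawAccel()]; numbers are written with enough digits that a
#' write/read round trip reproduces the arrays exactly.
#'
#' @param raw a [RawAccelSeries-class].
#' @param path output path.
#' @param dialect `"empatica_header"` or `"plain_xyz"`.
#' @return `path`, invisibly.
#' @export
writeRawAccel <- function(raw, path, dialect = c("empatica_header", "plain_xyz")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "empatica_header") {
    ts <- fmt(as.numeric(raw@startTime))
    writeLines(paste(rep(ts, 3L), collapse = ","), con)
    writeLines(paste(rep(fmt(raw@samplingRate), 3L), collapse = ","), con)
  }
  writeLines(paste(fmt(raw@x), fmt(raw@y), fmt(raw@z), sep = ","), con)
  invisible(path)
}

#' Per-minute activity counts from raw acceleration
#'
#' Computes, for every complete minute (`samplingRate * 60` samples, 1920 at
#' 32 Hz), the mean of `|sqrt(x^2 + y^2 + z^2) - gravity|`. The trailing
#' partial minute, if any, is discarded.
#'
#' @param raw a [RawAccelSeries-class].
#' @param gravity gravity constant to subtract from the acceleration
#'   magnitude, in the units of the input (default 1.0 g).
#' @return An [ActivitySeries-class] of per-minute counts (all observed).
#' @examples
#' raw <- rawAccelSeries(numeric(1920), numeric(1920), rep(2, 1920))
#' counts(minuteCounts(raw))  # |2 - 1| = 1
#' @export
minuteCounts <- function(raw, gravity = 1.0) {
  stopifnot(is(raw, "RawAccelSeries"))
  if (raw@samplingRate <= 0) stop("sampling rate must be positive")
  spm <- raw@samplingRate * 60
  if (abs(spm - round(spm)) > 1e-9)
    stop("sampling rate must yield a whole number of samples per minute")
  spm <- as.integer(round(spm))
  n <- length(raw@x)
  nMin <- n %/% spm
  if (nMin < 1L) stop("fewer samples than one full minute")
  dev <- abs(sqrt(raw@x^2 + raw@y^2 + raw@z^2) - gravity)
  cnt <- colMeans(matrix(dev[seq_len(nMin * spm)], nrow = spm, ncol = nMin))
  activitySeries(cnt, missing = rep(FALSE, nMin), startTime = raw@startTime)
}

#' Impute missing minutes by the observed mean
#'
#' A series is acceptable when its missing fraction is strictly below
#' `maxMissingFrac` (default 5%); each missing minute is then replaced by the
#' arithmetic mean of the observed minutes and the mask cleared. Series at or
#' above the threshold are rejected with an error of class
#' `"actimood_missing_rejection"` carrying the fraction in its `fraction`
#' field.
#'
#' @param series an [ActivitySeries-class].
#' @param maxMissingFrac rejection threshold on the missing fraction.
#' @return The imputed [ActivitySeries-class] (unchanged if nothing missing).
#' @export
imputeMissing <- function(series, maxMissingFrac = 0.05) {
  stopifnot(is(series, "ActivitySeries"))
  n <- length(series@counts)
  if (n == 0L) stop("empty series")
  frac <- mean(series@missing)
  if (frac == 0) return(series)
  if (frac == 1) stop("all values missing; nothing to impute from")
  if (frac >= maxMissingFrac)
    stop(errorCondition(
      sprintf("series rejected: %.2f%% missing (threshold < %.2f%%)",
              100 * frac, 100 * maxMissingFrac),
      fraction = frac,
      class = c("actimood_missing_rejection", "error", "condition")))
  obsMean <- mean(series@counts[!series@missing])
  series@counts[series@missing] <- obsMean
  series@missing[] <- FALSE
  validObject(series)
  series
}

#' Extract a contiguous epoch from a series
#'
#' Returns the sub-series `[offset, offset + duration)` with metadata carried
#' over and the epoch label attached. The start timestamp is advanced by the
#' offset.
#'
#' @param series an [ActivitySeries-class].
#' @param spec an [EpochSpec-class].
#' @return The extracted [ActivitySeries-class].
#' @examples
#' s <- activitySeries(1:10)
#' nMinutes(extractEpoch(s, epochSpec(2, 5)))
#' @export
extractEpoch <- function(series, spec) {
  stopifnot(is(series, "ActivitySeries"), is(spec, "EpochSpec"))
  n <- length(series@counts)
  if (spec@offset + spec@duration > n)
    stop(sprintf("epoch '%s' (offset %d + duration %d) exceeds series length %d",
                 spec@label, spec@offset, spec@duration, n))
  idx <- seq.int(spec@offset + 1L, spec@offset + spec@duration)
  activitySeries(series@counts[idx], missing = series@missing[idx],
                 startTime = series@startTime + spec@offset * 60,
                 subjectId = series@subjectId, state = series@state,
                 epochLabel = spec@label)
}

#' Read / write a per-minute activity CSV
#'
#' The dialect is `timestamp,counts` with a header, ISO-8601 minute
#' timestamps (`YYYY-MM-DDTHH:MM`, UTC) and an empty counts field for a
#' missing minute. Lines starting with `#` are treated as comments (the
#' pipeline writes a provenance hash there).
#'
#' @param path file path.
#' @param subjectId,state labels attached to the returned series.
#' @return `readActivityCSV`: an [ActivitySeries-class].
#' @export
readActivityCSV <- function(path, subjectId = "", state = "unlabelled") {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("character", "character"))
  if (!identical(names(df), c("timestamp", "counts")))
    stop("expected header 'timestamp,counts' in ", path)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  if (anyNA(ts)) stop("malformed ISO-8601 minute timestamp in ", path)
  vals <- suppressWarnings(as.numeric(df$counts))
  miss <- is.na(vals) | !nzchar(trimws(df$counts))
  if (any(is.na(vals) & nzchar(trimws(df$counts))))
    stop("non-numeric counts value in ", path)
  activitySeries(vals, missing = miss, startTime = ts[1L],
                 subjectId = subjectId, state = state)
}

#' @rdname readActivityCSV
#' @param series an [ActivitySeries-class] to write.
#' @param comment optional comment lines written at the top, prefixed `# `.
#' @return `writeActivityCSV`: `path`, invisibly.
#' @export
writeActivityCSV <- function(series, path, comment = character()) {
  stopifnot(is(series, "ActivitySeries"))
  n <- length(series@counts)
  ts <- format(series@startTime + (seq_len(n) - 1L) * 60,
               "%Y-%m-%dT%H:%M", tz = "UTC")
  vals <- ifelse(series@missing, "", sprintf("%.17g", series@counts))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines("timestamp,counts", con)
  writeLines(paste(ts, vals, sep = ","), con)
  invisible(path)
}
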