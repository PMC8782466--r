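#' Feature set of one activity epoch
#'
#' Computes the full feature row of one epoch of one recording: the five
#' [variabilityFeatures()], [sampleEntropy()] and [symbolicDynamicsCount()],
#' and the [graphMetrics()] for every requested k (columns suffixed `_k<k>`,
#' e.g. `bridges_k5`).
#'
#' @param series an [ActivitySeries-class] with no missing minutes.
#' @param ks integer vector of neighbourhood sizes.
#' @param complexity a [complexityConfig()].
#' @param ratioThreshold,comparator,zeroRule passed to
#'   [buildSimilarityGraph()].
#' @return One-row data.frame with `subject_id`, `state`, `epoch` and all
#'   feature columns.
#' @export
extractFeatures <- function(series, ks = c(2L, 5L),
                            complexity = complexityConfig(),
                            ratioThreshold = 1.2,
                            comparator = c("strict_less", "less_equal"),
                            zeroRule = c("both_zero_similar",
                                         "any_zero_dissimilar")) {
  comparator <- match.arg(comparator)
  zeroRule <- match.arg(zeroRule)
  stopifnot(is(series, "ActivitySeries"))
  vf <- variabilityFeatures(series)
  se <- sampleEntropy(series, complexity)
  sc <- symbolicDynamicsCount(series, complexity)
  row <- data.frame(subject_id = subjectId(series), state = moodState(series),
                    epoch = epochLabel(series), stringsAsFactors = FALSE)
  row <- cbind(row, as.data.frame(as.list(vf)),
               sample_entropy = as.numeric(se), symbolic_count = sc)
  gm <- metricsForKs(series, ks, ratioThreshold, comparator, zeroRule)
  for (i in seq_along(ks)) {
    vals <- gm[i, setdiff(names(gm), "k"), drop = FALSE]
    names(vals) <- paste0(names(vals), "_k", ks[i])
    row <- cbind(row, vals)
  }
  rownames(row) <- NULL
  row
}

#' Study configuration
#'
#' Reads (or builds) the single declarative configuration that drives the
#' pipeline. Defaults follow the study design: a 1190-minute full epoch taken
#' from the start of each recording, 120-minute morning (08:00-10:00) and
#' evening (20:00-22:00) clock windows, k in {2, 5, 40} for the full epoch
#' and {2, 5} for the short epochs, ratio threshold 1.2, strict distance
#' comparator, significance level 0.05 (with a Bonferroni family size of 4
#' for within-state morning/evening comparisons), and one root seed feeding
#' all randomness.
#'
#' @param path optional YAML file; fields present override the defaults.
#' @param ... named overrides applied after the file.
#' @return A list of class `"StudyConfig"`.
#' @export
studyConfig <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    out_dir = "actimood-out",
    n_pairs = 14L,
    minutes = 1440L,
    full_duration = 1190L,
    epoch_duration_short = 120L,
    morning_clock = "08:00",
    evening_clock = "20:00",
    ks_full = c(2L, 5L, 40L),
    ks_short = c(2L, 5L),
    ratio_threshold = 1.2,
    comparator = "strict_less",
    zero_rule = "both_zero_similar",
    max_missing_frac = 0.05,
    gravity = 1.0,
    alpha = 0.05,
    bonferroni_m = 4L,
    complexity = list(m = 2L, r_frac = 0.2, n_symbols = 6L,
                      word_length = 3L, clip_sd = 3)
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "StudyConfig"
  cfg
}

#' @rdname studyConfig
#' @param config a `"StudyConfig"`.
#' @return `configHash`: an 8-hex-digit provenance fingerprint of the
#'   configuration (djb2-style rolling hash; for output provenance headers,
#'   not cryptography).
#' @export
configHash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 5381
  for (code in utf8ToInt(s)) h <- (h * 33 + code) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Minutes from a series start time to the next occurrence of clock "HH:MM".
.clockOffset <- function(start, clock) {
  hm <- as.integer(strsplit(clock, ":")[[1L]])
  target <- hm[1L] * 60L + hm[2L]
  lt <- as.POSIXlt(start, tz = "UTC")
  cur <- lt$hour * 60L + lt$min
  (target - cur) %% 1440L
}

.complexityFromConfig <- function(config) {
  cc <- config$complexity
  complexityConfig(m = cc$m, rFrac = cc$r_frac, nSymbols = cc$n_symbols,
                   wordLength = cc$word_length, clipSd = cc$clip_sd)
}

# The epoch specs a recording is analysed under, resolved against its start.
.epochSpecs <- function(config, series) {
  list(
    full = epochSpec(0L, config$full_duration,
                     sprintf("full-%d", config$full_duration)),
    morning = epochSpec(.clockOffset(startTime(series), config$morning_clock),
                        config$epoch_duration_short, "morning-120"),
    evening = epochSpec(.clockOffset(startTime(series), config$evening_clock),
                        config$epoch_duration_short, "evening-120")
  )
}

#' Simulate a cohort to disk
#'
#' Generates the paired synthetic cohort of `config$n_pairs` subjects and
#' writes one per-minute CSV per recording plus a `manifest.csv`
#' (subject_id, state, file). Every output carries the configuration hash in
#' a `#` header line.
#'
#' @param config a [studyConfig()].
#' @return Path to the manifest, invisibly.
#' @export
runSimulate <- function(config = studyConfig()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  coh <- simulateCohort(config$n_pairs,
                        manic = manicPreset(config$minutes),
                        euthymic = euthymicPreset(config$minutes),
                        seed = config$seed)
  files <- character(length(coh$recordings))
  for (i in seq_along(coh$recordings)) {
    s <- coh$recordings[[i]]
    fn <- sprintf("%s_%s.csv", subjectId(s), moodState(s))
    writeActivityCSV(s, file.path(config$out_dir, fn),
                     comment = paste("config_hash:", hash))
    files[i] <- fn
    message(sprintf("simulate: %s %s (%d min)", subjectId(s), moodState(s),
                    nMinutes(s)))
  }
  manifest <- cbind(coh$manifest[c("subject_id", "state")], file = files)
  mpath <- file.path(config$out_dir, "manifest.csv")
  con <- file(mpath, "w")
  writeLines(paste("# config_hash:", hash), con)
  utils::write.csv(manifest, con, row.names = FALSE)
  close(con)
  invisible(mpath)
}

#' Extract the feature table of a cohort
#'
#' For every recording in the manifest: read the per-minute CSV, impute
#' missing minutes (strict <5% rule), extract the full / morning / evening
#' epochs and compute [extractFeatures()] per epoch (full-epoch k values for
#' the full window, short-epoch k values for the 120-minute windows). Per-
#' recording failures are logged and the run continues; if any recording
#' failed, the function errors after writing what succeeded.
#'
#' @param config a [studyConfig()].
#' @param manifestPath path to the manifest CSV (default: the one
#'   [runSimulate()] writes under `config$out_dir`).
#' @return Path to `features.csv`, invisibly.
#' @export
runExtract <- function(config = studyConfig(),
                       manifestPath = file.path(config$out_dir, "manifest.csv")) {
  manifest <- utils::read.csv(manifestPath, comment.char = "#",
                              stringsAsFactors = FALSE)
  hash <- configHash(config)
  cc <- .complexityFromConfig(config)
  rows <- list(); failures <- character()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      s <- readActivityCSV(file.path(dirname(manifestPath), rec$file),
                           subjectId = rec$subject_id, state = rec$state)
      s <- imputeMissing(s, config$max_missing_frac)
      specs <- .epochSpecs(config, s)
      lapply(names(specs), function(en) {
        ks <- if (en == "full") config$ks_full else config$ks_short
        extractFeatures(extractEpoch(s, specs[[en]]), ks = ks,
                        complexity = cc,
                        ratioThreshold = config$ratio_threshold,
                        comparator = config$comparator,
                        zeroRule = config$zero_rule)
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s/%s: %s", rec$subject_id, rec$state,
                                      conditionMessage(res)))
      message(sprintf("extract: FAILED %s %s: %s", rec$subject_id, rec$state,
                      conditionMessage(res)))
    } else {
      rows <- c(rows, res)
      message(sprintf("extract: %s %s (3 epochs, %.2fs)", rec$subject_id,
                      rec$state, proc.time()[["elapsed"]] - t0))
    }
  }
  feats <- do.call(rbind, rows)
  fpath <- file.path(dirname(manifestPath), "features.csv")
  con <- file(fpath, "w")
  writeLines(paste("# config_hash:", hash), con)
  utils::write.csv(feats, con, row.names = FALSE)
  close(con)
  if (length(failures))
    stop("extraction failed for ", length(failures), " recording(s):\n  ",
         paste(failures, collapse = "\n  "))
  invisible(fpath)
}

#' Compare mood states and write the report files
#'
#' Produces, per epoch, the state-comparison CSV (mean (SD) per state, test,
#' p, significance flag at `config$alpha`), an aligned text report mirroring
#' the published table layout, and the Pearson correlation matrices (r and p)
#' of the manic morning features.
#'
#' @param config a [studyConfig()].
#' @param featuresPath path to the feature table from [runExtract()].
#' @return Named character vector of output paths, invisibly.
#' @export
runCompare <- function(config = studyConfig(),
                       featuresPath = file.path(config$out_dir, "features.csv")) {
  feats <- utils::read.csv(featuresPath, comment.char = "#",
                           stringsAsFactors = FALSE)
  hash <- configHash(config)
  outDir <- dirname(featuresPath)
  paths <- character()
  txt <- character()
  for (epoch in unique(feats$epoch)) {
    tab <- stateComparisonReport(feats, epoch, alpha = config$alpha)
    rpath <- file.path(outDir, sprintf("report_%s.csv", epoch))
    con <- file(rpath, "w")
    writeLines(paste("# config_hash:", hash), con)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    paths[paste0("report_", epoch)] <- rpath
    txt <- c(txt, sprintf("== %s ==", epoch), formatReportText(tab), "")
    message(sprintf("compare: %s (%d features)", epoch, nrow(tab)))
  }
  tpath <- file.path(outDir, "report.txt")
  writeLines(c(paste("# config_hash:", hash), txt), tpath)
  paths["report_text"] <- tpath
  mm <- feats[feats$state == "manic" & grepl("^morning", feats$epoch), ]
  if (nrow(mm) >= 3L) {
    featCols <- names(mm)[vapply(mm, is.numeric, logical(1))]
    constant <- featCols[vapply(mm[featCols], function(v) stats::sd(v) == 0,
                                logical(1))]
    if (length(constant))
      message("compare: dropping constant feature(s) from the correlation: ",
              paste(constant, collapse = ", "))
    featCols <- setdiff(featCols, constant)
    cm <- pearsonMatrix(mm[featCols])
    for (what in c("r", "p")) {
      cpath <- file.path(outDir, sprintf("correlation_manic_morning_%s.csv", what))
      con <- file(cpath, "w")
      writeLines(paste("# config_hash:", hash), con)
      utils::write.csv(round(cm[[what]], 6), con)
      close(con)
      paths[paste0("correlation_", what)] <- cpath
    }
  }
  invisible(paths)
}

#' Worked similarity-graph example
#'
#' Builds the similarity graph of the 11-point reference series
#' S = (9, 10, 10, 8, 7, 8, 7, 6, 5, 10, 9) with k = 5 and the strict
#' max/min < 1.2 criterion, prints the six graph measures and returns them
#' invisibly. Expected: 13 edges, 3 components, 2 bridges, 3 missing direct
#' edges, 1 isolated point, 6 triangles.
#'
#' @return Named numeric vector of [graphMetrics()], invisibly.
#' @examples
#' figure1Check()
#' @export
figure1Check <- function() {
  s <- c(9, 10, 10, 8, 7, 8, 7, 6, 5, 10, 9)
  g <- buildSimilarityGraph(s, k = 5)
  m <- graphMetrics(g)
  cat("similarity graph of S = (9,10,10,8,7,8,7,6,5,10,9), k = 5:\n")
  for (nm in names(m)) cat(sprintf("  %-15s %g\n", nm, m[[nm]]))
  invisible(m)
}
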