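# Exact two-sided p-value for the Wilcoxon signed-rank statistic V (sum of
# positive midranks) conditional on the observed midranks, by the shift
# (generating-function) algorithm. Midranks are doubled so the support is
# integer even under ties.
.wilcoxExactP <- function(ranks, V) {
  s <- as.integer(round(2 * ranks))
  tot <- sum(s)
  f <- numeric(tot + 1L)  # f[w + 1] = number of sign assignments with 2V = w
  f[1L] <- 1
  for (si in s) {
    shifted <- c(numeric(si), f[seq_len(tot + 1L - si)])
    f <- f + shifted
  }
  f <- f / 2^length(s)
  w <- as.integer(round(2 * V))
  pLe <- sum(f[seq_len(w + 1L)])
  pGe <- sum(f[seq.int(w + 1L, tot + 1L)])
  min(1, 2 * min(pLe, pGe))
}

#' Paired within-subject comparison of two feature vectors
#'
#' Compares per-subject feature values between two conditions, paired by
#' position. `"paired_t"` is the paired Student t-test (differences, n - 1
#' df, two-sided). `"wilcoxon_signed_rank"` drops zero differences, ranks the
#' absolute differences with midranks for ties, and uses the exact
#' conditional null distribution of the signed-rank sum for up to 25 nonzero
#' differences (a tie-corrected normal approximation beyond that); used for
#' heavily skewed features such as 3-clique counts.
#'
#' Degenerate inputs -- zero-variance differences for the t-test, all-zero
#' differences for the Wilcoxon -- raise an error of class
#' `"actimood_degenerate_input"`.
#'
#' @param a,b numeric vectors of equal length (n >= 2), paired by subject.
#' @param method `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @return A list of class `"TestResult"`: `method`, `statistic` (t, or the
#'   signed-rank sum V / z), `p_value` (two-sided), `n_pairs`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`.
#' @examples
#' pairedComparison(c(1, 2, 3, 4, 5), c(2, 2, 4, 3, 6))
#' @export
pairedComparison <- function(a, b, method = c("paired_t", "wilcoxon_signed_rank")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing values in paired data")
  d <- a - b
  degenerate <- function(msg) stop(errorCondition(
    msg, class = c("actimood_degenerate_input", "error", "condition")))
  if (method == "paired_t") {
    if (stats::sd(d) == 0)
      degenerate("paired t-test undefined: differences have zero variance")
    tt <- stats::t.test(a, b, paired = TRUE)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    dz <- d[d != 0]
    nz <- length(dz)
    if (nz == 0L)
      degenerate("Wilcoxon signed-rank undefined: all differences are zero")
    r <- rank(abs(dz))
    V <- sum(r[dz > 0])
    if (nz <= 25L) {
      statistic <- V
      p <- .wilcoxExactP(r, V)
    } else {
      mu <- nz * (nz + 1) / 4
      tie <- table(r)
      sig2 <- nz * (nz + 1) * (2 * nz + 1) / 24 - sum(tie^3 - tie) / 48
      z <- (V - mu) / sqrt(sig2)
      statistic <- z
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  structure(list(method = method, statistic = statistic, p_value = p,
                 n_pairs = length(a),
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b)),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %d pairs)\n",
              x$method, x$statistic, x$p_value, x$n_pairs))
  cat(sprintf("  a: %.3f (%.3f)   b: %.3f (%.3f)\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  invisible(x)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param mTests number of tests in the family, integer >= 1.
#' @return `alpha / mTests` (e.g. 0.05 / 4 = 0.0125 for the four
#'   morning-vs-evening within-state comparisons).
#' @examples
#' bonferroniAlpha(0.05, 4)
#' @export
bonferroniAlpha <- function(alpha, mTests) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(mTests) || length(mTests) != 1L || mTests < 1)
    stop("mTests must be an integer >= 1")
  alpha / mTests
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Computes all pairwise Pearson correlations between the columns of a
#' feature table, with two-sided p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df. Zero-variance columns are
#' flagged: their r and p entries are `NA` and a warning names them.
#'
#' @param features numeric data.frame or matrix, >= 3 rows (subjects), no
#'   missing values.
#' @return A list of class `"CorrelationMatrix"`: `r` (symmetric, unit
#'   diagonal), `p` (two-sided, `NA` diagonal), `n`.
#' @export
pearsonMatrix <- function(features) {
  m <- as.matrix(features)
  if (!is.numeric(m)) stop("features must be numeric")
  if (anyNA(m)) stop("missing feature values")
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 subjects")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance feature(s) flagged undefined: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(m))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0  # perfect correlation off the diagonal
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "CorrelationMatrix")
}

#' State-comparison report for a paired feature table
#'
#' Builds the mood-state comparison table: one row per feature with
#' mean (SD) per state, the test used, its statistic, the two-sided p-value
#' and a significance flag at `alpha`. Triangle (3-clique) features use the
#' Wilcoxon signed-rank test; every other feature uses the paired t-test.
#' Subjects lacking either state are listed in a warning and excluded.
#' Degenerate features (zero-variance differences) are flagged with `NA`
#' p-values rather than dropped.
#'
#' @param features data.frame with columns `subject_id`, `state`, `epoch` and
#'   numeric feature columns (as produced by [extractFeatures()] /
#'   [runExtract()]).
#' @param epoch epoch label to compare (a value of `features$epoch`).
#' @param alpha per-test significance threshold (default 0.05; pass a
#'   [bonferroniAlpha()] value for corrected families).
#' @param stateA,stateB the two states; differences are `stateA - stateB`.
#' @return data.frame of class `"StateComparisonReport"` with one row per
#'   feature.
#' @export
stateComparisonReport <- function(features, epoch, alpha = 0.05,
                                  stateA = "manic", stateB = "euthymic") {
  stopifnot(is.data.frame(features),
            all(c("subject_id", "state", "epoch") %in% names(features)))
  df <- features[features$epoch == epoch, , drop = FALSE]
  if (!nrow(df)) stop("no rows for epoch '", epoch, "'")
  subjects <- unique(df$subject_id)
  hasBoth <- vapply(subjects, function(s) {
    all(c(stateA, stateB) %in% df$state[df$subject_id == s])
  }, logical(1))
  if (any(!hasBoth)) {
    warning("excluding unpaired subject(s): ",
            paste(subjects[!hasBoth], collapse = ", "))
    subjects <- subjects[hasBoth]
  }
  if (length(subjects) < 2L) stop("fewer than 2 paired subjects")
  featCols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                      c("subject_id"))
  ord <- order(match(df$subject_id, subjects))
  df <- df[ord, , drop = FALSE]
  A <- df[df$state == stateA & df$subject_id %in% subjects, , drop = FALSE]
  B <- df[df$state == stateB & df$subject_id %in% subjects, , drop = FALSE]
  A <- A[match(subjects, A$subject_id), , drop = FALSE]
  B <- B[match(subjects, B$subject_id), , drop = FALSE]
  rows <- lapply(featCols, function(f) {
    method <- if (grepl("^triangles", f)) "wilcoxon_signed_rank" else "paired_t"
    a <- A[[f]]; b <- B[[f]]
    base <- data.frame(feature = f,
                       mean_a = mean(a), sd_a = stats::sd(a),
                       mean_b = mean(b), sd_b = stats::sd(b),
                       method = method, stringsAsFactors = FALSE)
    if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
      cbind(base, statistic = NA_real_, p_value = NA_real_,
            n_pairs = length(subjects), significant = NA)
    } else {
      res <- tryCatch(pairedComparison(a, b, method),
                      actimood_degenerate_input = function(e) NULL)
      if (is.null(res))
        cbind(base, statistic = NA_real_, p_value = NA_real_,
              n_pairs = length(subjects), significant = NA)
      else
        cbind(base, statistic = res$statistic, p_value = res$p_value,
              n_pairs = res$n_pairs, significant = res$p_value < alpha)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", stateA)
  names(out)[names(out) == "sd_a"] <- paste0("sd_", stateA)
  names(out)[names(out) == "mean_b"] <- paste0("mean_", stateB)
  names(out)[names(out) == "sd_b"] <- paste0("sd_", stateB)
  attr(out, "epoch") <- epoch
  attr(out, "alpha") <- alpha
  class(out) <- c("StateComparisonReport", "data.frame")
  out
}

#' Render a state-comparison report as an aligned text table
#'
#' Mirrors the mean (SD) / mean (SD) / p column layout of the published
#' report tables.
#'
#' @param report a [stateComparisonReport()] result.
#' @return Character vector of lines, invisibly; printed if `print = TRUE`.
#' @param print whether to cat the table.
#' @export
formatReportText <- function(report, print = FALSE) {
  stopifnot(inherits(report, "StateComparisonReport"))
  msd <- function(m, s) sprintf("%.2f (%.2f)", m, s)
  stateCols <- grep("^mean_", names(report), value = TRUE)
  sA <- sub("^mean_", "", stateCols[1L]); sB <- sub("^mean_", "", stateCols[2L])
  body <- data.frame(
    Feature = report$feature,
    A = msd(report[[paste0("mean_", sA)]], report[[paste0("sd_", sA)]]),
    B = msd(report[[paste0("mean_", sB)]], report[[paste0("sd_", sB)]]),
    p = ifelse(is.na(report$p_value), "degenerate",
               ifelse(report$significant, sprintf("%.3f *", report$p_value),
                      sprintf("%.3f", report$p_value))))
  names(body)[2:3] <- c(sA, sB)
  widths <- pmax(nchar(names(body)), apply(nchar(as.matrix(body)), 2L, max))
  pad <- function(v, w) formatC(v, width = w, flag = "-")
  lines <- c(
    paste(mapply(pad, names(body), widths), collapse = "  "),
    paste(mapply(pad, rep("-", 4L), widths,
                 MoreArgs = list()), collapse = "  "),
    apply(mapply(pad, body, widths), 1L, paste, collapse = "  "))
  lines[2L] <- gsub(" ", "-", lines[2L])
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
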