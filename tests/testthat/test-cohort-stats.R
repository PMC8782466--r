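test_that("paired t evaluates the closed-form statistic", {
  res <- pairedComparison(c(1, 2, 3, 4, 5), c(2, 2, 4, 3, 6))
  expect_equal(res$statistic, -1.0, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-1, df = 4), tolerance = 1e-12)
  expect_equal(res$n_pairs, 5)
  expect_equal(res$mean_a, 3)
  expect_equal(res$mean_b, 3.4)
})

test_that("degenerate paired inputs raise classed errors", {
  err <- tryCatch(pairedComparison(c(1, 2, 3, 4), c(2, 3, 4, 5)),
                  condition = identity)
  expect_s3_class(err, "actimood_degenerate_input")  # constant differences
  err2 <- tryCatch(pairedComparison(c(1, 2, 3), c(1, 2, 3),
                                    "wilcoxon_signed_rank"),
                   condition = identity)
  expect_s3_class(err2, "actimood_degenerate_input")  # all-zero differences
})

test_that("paired t is invariant to adding a common constant to both states", {
  set.seed(61)
  a <- rlnorm(12); b <- rlnorm(12)
  r1 <- pairedComparison(a, b)
  r2 <- pairedComparison(a + 100, b + 100)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("exact Wilcoxon matches stats::wilcox.test on tie-free data", {
  set.seed(62)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    res <- pairedComparison(a, b, "wilcoxon_signed_rank")
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon with midrank ties matches full sign enumeration", {
  set.seed(63)
  for (i in 1:8) {
    n <- sample(5:11, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3, 5), n, replace = TRUE)
    res <- pairedComparison(d, numeric(n), "wilcoxon_signed_rank")
    expect_equal(res$p_value, oracleWilcoxP(d), tolerance = 1e-12)
  }
})

test_that("Wilcoxon p is invariant to monotone transforms of the magnitudes", {
  set.seed(64)
  d <- c(-4.2, 1.1, 2.5, -0.3, 6.8, 3.3, -2.2, 0.9)
  # order-preserving transform of |d| keeping signs
  d2 <- sign(d) * log1p(abs(d))
  r1 <- pairedComparison(d, numeric(8), "wilcoxon_signed_rank")
  r2 <- pairedComparison(d2, numeric(8), "wilcoxon_signed_rank")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$statistic, r2$statistic)
})

test_that("large-sample Wilcoxon falls back to a tie-corrected normal", {
  set.seed(65)
  a <- rnorm(40); b <- rnorm(40)
  res <- pairedComparison(a, b, "wilcoxon_signed_rank")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroniAlpha(0.05, 4), 0.0125)
  expect_equal(bonferroniAlpha(0.05, 1), 0.05)
  expect_equal(bonferroniAlpha(0.05, 10), 0.005)
  expect_error(bonferroniAlpha(0.05, 0), "mTests")
  expect_error(bonferroniAlpha(1.5, 2), "alpha")
})

test_that("Pearson matrix matches a from-scratch covariance computation", {
  set.seed(66)
  m <- matrix(rnorm(15 * 4), 15, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  cm <- pearsonMatrix(m)
  n <- 15
  for (i in 1:3) for (j in (i + 1):4) {
    xi <- m[, i]; xj <- m[, j]
    rij <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(cm$r[i, j], rij, tolerance = 1e-12)
    ref <- stats::cor.test(xi, xj)
    expect_equal(cm$p[i, j], ref$p.value, tolerance = 1e-12)
  }
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
})

test_that("perfect and inverted correlations and zero-variance flags", {
  x <- 1:10
  df <- data.frame(x = x, double = 2 * x, neg = -x, flat = rep(1, 10))
  expect_warning(cm <- pearsonMatrix(df), "flat")
  expect_equal(cm$r["x", "double"], 1)
  expect_equal(cm$r["x", "neg"], -1)
  expect_true(is.na(cm$r["x", "flat"]))
})

test_that("a null cohort (identical states) yields no significant rows", {
  set.seed(67)
  vals <- matrix(rlnorm(8 * 3), 8, 3,
                 dimnames = list(NULL, c("cv_percent", "sample_entropy",
                                         "triangles_k5")))
  feats <- rbind(
    data.frame(subject_id = sprintf("S%02d", 1:8), state = "manic",
               epoch = "full", vals),
    data.frame(subject_id = sprintf("S%02d", 1:8), state = "euthymic",
               epoch = "full", vals))
  rep <- stateComparisonReport(feats, "full")
  expect_true(all(is.na(rep$p_value)))     # degenerate: zero differences
  expect_false(any(rep$significant %in% TRUE))
  expect_equal(rep$method[rep$feature == "triangles_k5"], "wilcoxon_signed_rank")
  expect_equal(rep$method[rep$feature == "cv_percent"], "paired_t")
})

test_that("unpaired subjects are excluded with a warning; row count is structural", {
  set.seed(68)
  feats <- rbind(
    data.frame(subject_id = sprintf("S%02d", 1:6), state = "manic",
               epoch = "full", f1 = rlnorm(6), triangles_k2 = rpois(6, 20)),
    data.frame(subject_id = sprintf("S%02d", 1:5), state = "euthymic",
               epoch = "full", f1 = rlnorm(5), triangles_k2 = rpois(5, 30)))
  expect_warning(rep <- stateComparisonReport(feats, "full"), "S06")
  expect_equal(nrow(rep), 2L)  # one row per feature column
  expect_equal(unique(rep$n_pairs), 5)
  txt <- formatReportText(rep)
  expect_true(any(grepl("f1", txt)))
})

test_that("null calibration: paired t rejects at the nominal 5% rate", {
  set.seed(69)
  nRep <- 600
  rej <- 0L
  for (i in seq_len(nRep)) {
    d <- rnorm(10)
    a <- rnorm(10, 5); b <- a - d
    if (pairedComparison(a, b)$p_value < 0.05) rej <- rej + 1L
  }
  rate <- rej / nRep
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
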