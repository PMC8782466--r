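test_that("raw CSV round trip reproduces the arrays exactly, both dialects", {
  set.seed(42)
  n <- 3840  # two whole minutes at 32 Hz
  raw <- rawAccelSeries(rnorm(n), rnorm(n), rnorm(n, 1), samplingRate = 32,
                        startTime = as.POSIXct("2021-06-01 13:00:00", tz = "UTC"))
  for (dialect in c("empatica_header", "plain_xyz")) {
    f <- withr::local_tempfile(fileext = ".csv")
    writeRawAccel(raw, f, dialect)
    back <- readRawAccel(f, dialect, samplingRate = 32,
                         startTime = raw@startTime)
    expect_identical(back@x, raw@x)
    expect_identical(back@y, raw@y)
    expect_identical(back@z, raw@z)
    expect_equal(samplingRate(back), 32)
    expect_equal(as.numeric(startTime(back)), as.numeric(raw@startTime))
    expect_equal(length(back@x), 3840)
  }
})

test_that("malformed raw rows raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.1,0.2,0.3", "0.1,abc,0.3", "0.0,0.0,1.0"), f)
  expect_error(readRawAccel(f, "plain_xyz"), "line 2")
})

test_that("minuteCounts matches |sqrt(x^2+y^2+z^2) - gravity| block means", {
  spm <- 32 * 60
  # resting at 1 g along one axis -> count 0
  rest <- rawAccelSeries(numeric(spm), numeric(spm), rep(1, spm))
  expect_equal(counts(minuteCounts(rest, gravity = 1)), 0)
  # constant 2 g -> |2 - 1| = 1
  two <- rawAccelSeries(numeric(spm), numeric(spm), rep(2, spm))
  expect_equal(counts(minuteCounts(two, gravity = 1)), 1)
  # pseudo-random two minutes against the per-sample brute-force oracle
  set.seed(7)
  x <- rnorm(2 * spm); y <- rnorm(2 * spm); z <- rnorm(2 * spm, 1)
  raw <- rawAccelSeries(x, y, z)
  expect_equal(counts(minuteCounts(raw, gravity = 1)),
               oracleMinuteCounts(x, y, z, 32, 1), tolerance = 1e-12)
})

test_that("minuteCounts drops trailing partial minutes and is axis-symmetric", {
  spm <- 32 * 60
  set.seed(8)
  x <- rnorm(2 * spm + 500); y <- rnorm(2 * spm + 500); z <- rnorm(2 * spm + 500)
  raw <- rawAccelSeries(x, y, z)
  expect_equal(nMinutes(minuteCounts(raw)), 2L)
  perm <- rawAccelSeries(z, x, y)
  expect_equal(counts(minuteCounts(perm)), counts(minuteCounts(raw)))
  short <- rawAccelSeries(x[1:spm], y[1:spm], z[1:spm])
  expect_equal(nMinutes(minuteCounts(short)), 1L)
})

test_that("imputeMissing follows the strict <5% rule and preserves the observed mean", {
  set.seed(9)
  vals <- rlnorm(1190, 5, 0.5)
  # no missing -> identity
  s0 <- activitySeries(vals)
  expect_identical(counts(imputeMissing(s0)), vals)
  # 59 missing of 1190 (4.96%) -> accepted, filled with the observed mean
  miss59 <- sample(1190, 59)
  v <- vals; v[miss59] <- NA
  s59 <- activitySeries(v)
  imp <- imputeMissing(s59)
  obsMean <- mean(vals[-miss59])
  expect_equal(unname(counts(imp)[miss59]), rep(obsMean, 59))
  expect_false(any(missingMask(imp)))
  expect_equal(mean(counts(imp)[-miss59]), obsMean)  # observed values untouched
  # 60 missing (5.04%) -> rejected, carrying the fraction
  miss60 <- sample(1190, 60)
  v <- vals; v[miss60] <- NA
  err <- tryCatch(imputeMissing(activitySeries(v)), condition = identity)
  expect_s3_class(err, "actimood_missing_rejection")
  expect_equal(err$fraction, 60 / 1190)
})

test_that("imputation preserves the mean of the series exactly", {
  set.seed(10)
  vals <- rlnorm(500)
  idx <- sample(500, 20)
  v <- vals; v[idx] <- NA
  imp <- imputeMissing(activitySeries(v))
  expect_equal(mean(counts(imp)), mean(vals[-idx]), tolerance = 1e-12)
})

test_that("extractEpoch returns the requested window and composes", {
  set.seed(11)
  s <- activitySeries(rlnorm(1535), subjectId = "S01", state = "manic")
  full <- extractEpoch(s, epochSpec(0, 1190, "full-1190"))
  expect_equal(counts(full), counts(s)[1:1190])
  expect_equal(epochLabel(full), "full-1190")
  expect_equal(subjectId(full), "S01")
  expect_error(extractEpoch(s, epochSpec(500, 1190)), "exceeds")
  # suffix boundary window
  tail <- extractEpoch(s, epochSpec(1535 - 120, 120))
  expect_equal(counts(tail), counts(s)[1416:1535])
  # nested extraction equals one extraction with composed offsets
  inner <- extractEpoch(full, epochSpec(100, 120, "sub"))
  direct <- extractEpoch(s, epochSpec(100, 120, "sub"))
  expect_equal(counts(inner), counts(direct))
  expect_equal(as.numeric(startTime(inner)), as.numeric(startTime(direct)))
})

test_that("per-minute CSV round trip keeps values, missingness and timestamps", {
  set.seed(12)
  v <- rlnorm(100)
  v[c(3, 50)] <- NA
  s <- activitySeries(v, startTime = as.POSIXct("2021-02-03 13:04:00", tz = "UTC"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeActivityCSV(s, f, comment = "config_hash: abc")
  back <- readActivityCSV(f, subjectId = "S01", state = "euthymic")
  expect_identical(which(missingMask(back)), c(3L, 50L))
  expect_equal(counts(back)[!missingMask(back)], v[!is.na(v)])
  expect_equal(as.numeric(startTime(back)), as.numeric(s@startTime))
  expect_equal(moodState(back), "euthymic")
  expect_equal(readLines(f, n = 1), "# config_hash: abc")
})

test_that("ActivitySeries validity rejects negative observed counts", {
  expect_error(activitySeries(c(1, -2, 3)), "non-negative")
  expect_error(activitySeries(c(1, 2), state = "zoomy"), "state")
})
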