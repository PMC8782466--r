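fig1Series <- c(9, 10, 10, 8, 7, 8, 7, 6, 5, 10, 9)

test_that("the worked 11-point example reproduces all six published measures", {
  g <- buildSimilarityGraph(fig1Series, k = 5)
  e <- edgeMatrix(g)
  expect_equal(nrow(e), 13)
  # edge (1,4) present; (8,9) absent because 6/5 = 1.2 is not < 1.2
  expect_true(any(e[, 1] == 1 & e[, 2] == 4))
  expect_false(any(e[, 1] == 8 & e[, 2] == 9))
  m <- graphMetrics(g)
  expect_equal(unname(m["edges_total"]), 13)
  expect_equal(unname(m["components"]), 3)
  expect_equal(unname(m["bridges"]), 2)
  expect_equal(unname(m["missing_direct"]), 3)
  expect_equal(unname(m["isolated"]), 1)
  expect_equal(unname(m["triangles"]), 6)
  expect_equal(unname(m["mean_edges"]), 2 * 13 / 11)
})

test_that("a constant positive series under strict k = 2 yields a path graph", {
  g <- buildSimilarityGraph(rep(3, 25), k = 2)
  e <- edgeMatrix(g)
  expect_equal(nrow(e), 24)
  expect_true(all(e[, 2] - e[, 1] == 1))
  m <- graphMetrics(g)
  expect_equal(unname(m["components"]), 1)
  expect_equal(unname(m["bridges"]), 24)
  expect_equal(unname(m["triangles"]), 0)
  expect_equal(unname(m["missing_direct"]), 0)
  expect_equal(unname(m["isolated"]), 0)
  expect_equal(unname(m["mean_edges"]), 2 * 24 / 25)
})

test_that("edgeless graph metrics follow the empty-graph facts", {
  g <- buildSimilarityGraph(c(1, 10, 100, 1000, 10000), k = 3)
  m <- graphMetrics(g)
  expect_equal(unname(m["edges_total"]), 0)
  expect_equal(unname(m["components"]), 5)
  expect_equal(unname(m["isolated"]), 5)
  expect_equal(unname(m["missing_direct"]), 4)
  expect_equal(unname(m["bridges"]), 0)
  expect_equal(unname(m["triangles"]), 0)
})

test_that("edge sets match the all-pairs brute-force loop, both comparators", {
  set.seed(4242)
  for (seed in 1:10) {
    x <- randomSeries(sample(20:200, 1), seed)
    k <- sample(2:12, 1)
    for (strict in c(TRUE, FALSE)) {
      g <- buildSimilarityGraph(x, k,
                                comparator = if (strict) "strict_less" else "less_equal")
      got <- edgeMatrix(g)
      want <- oracleEdges(x, k, strict = strict)
      expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
      expect_equal(nrow(got), nrow(want))
    }
  }
})

test_that("zero-pair rules resolve the undefined max/min ratio as documented", {
  x <- c(0, 0, 5, 0)
  gBoth <- buildSimilarityGraph(x, k = 4, zeroRule = "both_zero_similar")
  e <- edgeMatrix(gBoth)
  expect_true(any(e[, 1] == 1 & e[, 2] == 2))   # (0,0) similar
  expect_false(any(e[, 1] == 2 & e[, 2] == 3))  # (0,5) dissimilar
  expect_true(any(e[, 1] == 2 & e[, 2] == 4))
  gNone <- buildSimilarityGraph(x, k = 4, zeroRule = "any_zero_dissimilar")
  expect_equal(nrow(edgeMatrix(gNone)), 0)
})

test_that("components, bridges and triangles agree with independent oracles", {
  set.seed(4343)
  for (seed in 1:25) {
    n <- sample(15:120, 1)
    x <- randomSeries(n, seed + 500)
    k <- sample(2:10, 1)
    g <- buildSimilarityGraph(x, k)
    m <- graphMetrics(g)
    ig <- igraphGraph(g)
    expect_equal(unname(m["components"]), igraph::count_components(ig))
    expect_equal(unname(m["bridges"]), oracleBridges(g))
    expect_equal(unname(m["triangles"]), oracleTriangles(g))
    expect_equal(unname(m["isolated"]), sum(igraph::degree(ig) == 0))
  }
})

test_that("edge sets are nested in k; components/edge counts are monotone", {
  set.seed(55)
  for (i in 1:5) {
    x <- randomSeries(150, i + 900)
    ks <- c(2, 3, 5, 10, 40)
    edgesByK <- lapply(ks, function(k)
      paste(edgeMatrix(buildSimilarityGraph(x, k))[, 1],
            edgeMatrix(buildSimilarityGraph(x, k))[, 2]))
    for (j in seq_len(length(ks) - 1))
      expect_true(all(edgesByK[[j]] %in% edgesByK[[j + 1]]))
    m <- metricsForKs(x, ks)
    expect_true(all(diff(m$edges_total) >= 0))
    expect_true(all(diff(m$components) <= 0))
    # missing_direct depends only on the ratio test, so it is k-invariant
    expect_equal(length(unique(m$missing_direct)), 1L)
  }
})

test_that("graph metrics are invariant to positive scaling of the series", {
  set.seed(56)
  x <- rlnorm(200, 3, 0.7)
  m1 <- graphMetrics(buildSimilarityGraph(x, 5))
  m2 <- graphMetrics(buildSimilarityGraph(1000 * x, 5))
  expect_equal(m1, m2)
})

test_that("mean-degree ceilings: < 2 under strict k = 2, <= 4 under less_equal", {
  set.seed(57)
  for (i in 1:5) {
    x <- rep(5, 100) + runif(100, 0, 0.01)  # nearly constant: densest case
    mS <- graphMetrics(buildSimilarityGraph(x, 2, comparator = "strict_less"))
    mL <- graphMetrics(buildSimilarityGraph(x, 2, comparator = "less_equal"))
    expect_lt(unname(mS["mean_edges"]), 2)
    expect_lte(unname(mL["mean_edges"]), 4)
    expect_gt(unname(mL["mean_edges"]), unname(mS["mean_edges"]))
  }
})

test_that("edge-list export writes 1-based 'u v' lines", {
  g <- buildSimilarityGraph(fig1Series, k = 5)
  f <- withr::local_tempfile(fileext = ".txt")
  writeEdgeList(g, f)
  lines <- readLines(f)
  expect_equal(length(lines), 13)
  expect_true(all(grepl("^[0-9]+ [0-9]+$", lines)))
  expect_true("1 4" %in% lines)
})
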