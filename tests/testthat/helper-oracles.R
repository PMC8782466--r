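# Independent brute-force oracles. Deliberately naive implementations,
# separate from the package's code paths.

# per-minute mean |magnitude - gravity| by an explicit per-sample loop
oracleMinuteCounts <- function(x, y, z, rate, gravity) {
  spm <- rate * 60
  nMin <- floor(length(x) / spm)
  out <- numeric(nMin)
  for (m in seq_len(nMin)) {
    acc <- 0
    for (s in seq_len(spm)) {
      i <- (m - 1) * spm + s
      acc <- acc + abs(sqrt(x[i]^2 + y[i]^2 + z[i]^2) - gravity)
    }
    out[m] <- acc / spm
  }
  out
}

# O(n^2) template-counting sample entropy (Chebyshev, <= r, no self-matches,
# both template sets over the first n - m positions)
oracleSampEn <- function(x, m, rFrac) {
  n <- length(x)
  r <- rFrac * sd(x)
  N <- n - m
  A <- 0; B <- 0
  for (i in seq_len(N - 1)) {
    for (j in seq.int(i + 1, N)) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# independent symbolisation + distinct-word count via string paste
oracleSymbolic <- function(x, nSymbols = 6, wordLength = 3, clipSd = 3) {
  mu <- mean(x); s <- sd(x)
  xc <- pmin(pmax(x, mu - clipSd * s), mu + clipSd * s)
  lo <- min(xc); hi <- max(xc)
  if (hi == lo) return(1L)
  edges <- seq(lo, hi, length.out = nSymbols + 1)
  sym <- findInterval(xc, edges, rightmost.closed = TRUE)
  words <- vapply(seq_len(length(x) - wordLength + 1), function(i)
    paste(sym[i:(i + wordLength - 1)], collapse = "-"), character(1))
  length(unique(words))
}

# all-pairs double loop over the edge criterion
oracleEdges <- function(x, k, ratio = 1.2, strict = TRUE) {
  n <- length(x)
  e <- NULL
  for (u in seq_len(n - 1)) {
    for (v in seq.int(u + 1, n)) {
      dOK <- if (strict) (v - u) < k else (v - u) <= k
      if (!dOK) next
      hi <- max(x[u], x[v]); lo <- min(x[u], x[v])
      sOK <- if (hi == 0) TRUE else if (lo == 0) FALSE else hi / lo < ratio
      if (sOK) e <- rbind(e, c(u, v))
    }
  }
  if (is.null(e)) matrix(integer(), ncol = 2) else e
}

# build the igraph equivalent with an explicit vertex count
igraphGraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(matrix(edgeMatrix(g), ncol = 2)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g@n)))
}

# bridges by removing each edge and recounting components with igraph
oracleBridges <- function(g) {
  ig <- igraphGraph(g)
  base <- igraph::count_components(ig)
  e <- edgeMatrix(g)
  if (!nrow(e)) return(0L)
  sum(vapply(seq_len(nrow(e)), function(i) {
    igraph::count_components(igraph::delete_edges(ig, i)) > base
  }, logical(1)))
}

# triangles by enumerating all node triples
oracleTriangles <- function(g) {
  e <- edgeMatrix(g)
  n <- g@n
  has <- matrix(FALSE, n, n)
  if (nrow(e)) has[e] <- TRUE
  has <- has | t(has)
  if (n < 3) return(0L)
  tri <- 0L
  cmb <- utils::combn(n, 3)
  for (i in seq_len(ncol(cmb))) {
    a <- cmb[1, i]; b <- cmb[2, i]; cc <- cmb[3, i]
    if (has[a, b] && has[b, cc] && has[a, cc]) tri <- tri + 1L
  }
  tri
}

# exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign vectors
oracleWilcoxP <- function(d) {
  dz <- d[d != 0]
  n <- length(dz)
  r <- rank(abs(dz))
  V <- sum(r[dz > 0])
  tot <- sum(r)
  Vs <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  pLe <- mean(Vs <= V + 1e-9)
  pGe <- mean(Vs >= V - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

randomSeries <- function(n, seed) {
  set.seed(seed)
  # right-skewed positive values with occasional ties and zeros
  v <- round(rlnorm(n, meanlog = 3, sdlog = 0.6))
  v[runif(n) < 0.02] <- 0
  v
}
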