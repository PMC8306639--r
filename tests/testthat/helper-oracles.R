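# Independent oracles and fixture builders used across tests. Everything is
# generated in code; no stored fixtures.

# small random count table
randomCountTable <- function(nOtu = 6, nSample = 4, lambda = 20, seed = 1) {
  withr::local_seed(seed)
  m <- matrix(rpois(nOtu * nSample, lambda), nOtu, nSample,
              dimnames = list(sprintf("OTU%02d", seq_len(nOtu)),
                              sprintf("s%02d", seq_len(nSample))))
  otuTable(m)
}

# all permutations of 1..n (recursive; used for exhaustive PERMANOVA p)
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# dense power-iteration principal eigenvector of an adjacency matrix,
# normalized to max 1
powerIterationScores <- function(A, iters = 10000, tol = 1e-14) {
  v <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    w <- A %*% v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  v <- as.numeric(v)
  v / max(v)
}

# Floyd-Warshall all-pairs shortest paths on an unweighted undirected graph
floydWarshall <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# brute-force global metrics from an adjacency matrix
bruteMetrics <- function(A) {
  n <- nrow(A)
  m <- sum(A[upper.tri(A)] > 0)
  d <- floydWarshall(A)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i < j && j < k && A[i, j] && A[j, k] && A[i, k])
          triangles <- triangles + 1
      }
    }
    deg <- sum(A[i, ] > 0)
    triples <- triples + choose(deg, 2)
  }
  list(nNodes = n, nEdges = m,
       density = if (n >= 2) 2 * m / (n * (n - 1)) else NA_real_,
       transitivity = if (triples > 0) 3 * triangles / triples else NA_real_,
       diameter = if (length(finite)) max(finite) else NA_real_,
       averagePathLength = if (length(finite)) mean(finite) else NA_real_)
}

# build a CoocNetwork directly from an adjacency matrix by fabricating a
# fully-significant CorrelationResult (exercises the real buildNetwork path)
networkFromAdjacency <- function(A, ids = sprintf("n%02d", seq_len(nrow(A)))) {
  n <- nrow(A)
  dimnames(A) <- list(ids, ids)
  r <- matrix(0, n, n, dimnames = dimnames(A))
  r[A > 0] <- 0.9
  diag(r) <- 1
  pRaw <- matrix(1, n, n, dimnames = dimnames(A))
  pRaw[A > 0] <- 0
  diag(pRaw) <- NA_real_
  pAdj <- pRaw
  corr <- new("CorrelationResult", otuIds = ids, r = r, pRaw = pRaw,
              pAdj = pAdj, nPermutations = 100L, pseudocount = FALSE,
              zeroVariance = rep(FALSE, n), seed = NA_integer_)
  buildNetwork(corr, alpha = 0.01)
}

# random connected-ish adjacency matrix
randomAdjacency <- function(n, p = 0.15, seed = 1) {
  withr::local_seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# ---- shared heavy simulations (computed lazily, reused across tests) ------

.simCache <- new.env(parent = emptyenv())

# 50-seed simulation on the calibration-shape table (100 OTUs, 20 samples,
# depth 10,000) with one planted 5-OTU block at latent rho 0.95; B = 200.
blockRecoverySim <- function() {
  if (!is.null(.simCache$block)) return(.simCache$block)
  spec <- presetSpec("mini", blocks = list(list(otus = 1:5, rho = 0.95)))
  res <- lapply(1:50, function(s) {
    sim <- simulateOtuTable(spec, seed = s)
    corr <- permutationPvalues(relativeAbundance(sim$table), B = 200,
                               seed = s + 1000)
    net <- buildNetwork(corr, alpha = 0.01)
    evaluateRecovery(net, sim$truth)
  })
  .simCache$block <- res
  res
}

# 50-seed hub-and-spoke simulation: 1 hub + 15 spokes at latent rho 0.9,
# 30 background OTUs in 15 disjoint correlated pairs; B = 200.
hubRecoverySim <- function() {
  if (!is.null(.simCache$hub)) return(.simCache$hub)
  bgPairs <- lapply(seq(17, 45, by = 2),
                    function(i) list(otus = c(i, i + 1), rho = 0.9))
  spec <- syntheticSpec(nOtus = 46, depth = 10000, nSamples = 20,
                        hubs = list(list(hub = 1, spokes = 2:16, rho = 0.9)),
                        blocks = bgPairs)
  res <- lapply(1:50, function(s) {
    sim <- simulateOtuTable(spec, seed = s)
    corr <- permutationPvalues(relativeAbundance(sim$table), B = 200,
                               seed = s + 1000)
    net <- buildNetwork(corr, alpha = 0.01)
    hs <- hubScores(net)
    list(attainsMax = unname(hs$scores["OTU_0001"]) >=
           max(hs$scores) - 1e-12,
         top = hs$topHubs)
  })
  .simCache$hub <- res
  res
}
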