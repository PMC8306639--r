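# Pearson matrix, permutation calibration, BH, network building, hub scores,
# graph metrics.

test_that("pearsonMatrix matches hand-evaluated coefficients", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1),
             d = c(1, 3, 2), e = c(5, 5, 5))
  colnames(m) <- c("s1", "s2", "s3")
  r <- pearsonMatrix(otuTable(m))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "d"], 0.5)
  expect_equal(unname(diag(r)[1:4]), rep(1, 4))
  # zero-variance OTU is flagged undefined
  expect_true(all(is.na(r["e", ])))
  expect_error(pearsonMatrix(otuTable(m[, 1:2])), "3 samples")
})

test_that("bhAdjust reproduces hand-stepped adjustments", {
  expect_equal(bhAdjust(0.037), 0.037)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 4 * 0.02 / 3, 0.04))
  # order-agnostic
  p <- c(0.04, 0.005, 0.02, 0.011)
  expect_equal(bhAdjust(p), c(0.04, 0.02, 4 * 0.02 / 3, 0.022))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("permutation p-values behave at the degenerate and duplicate extremes", {
  withr::local_seed(2)
  base <- matrix(rnorm(8 * 10), 8, 10,
                 dimnames = list(sprintf("o%d", 1:8), sprintf("s%d", 1:10)))
  m <- abs(base)
  m[1, ] <- m[2, ]          # duplicate pair, r = 1
  m[8, ] <- 3               # constant row
  corr <- permutationPvalues(otuTable(m), B = 100, seed = 5)
  pr <- slot(corr, "pRaw")
  expect_equal(pr["o1", "o2"], 0)            # null never reaches |r| = 1
  expect_true(all(is.na(pr["o8", ])))        # constant row untestable
  expect_true(all(is.na(slot(corr, "r")["o8", ])))
  # symmetry and the pAdj >= pRaw invariant
  expect_equal(pr, t(pr))
  expect_true(all(slot(corr, "pAdj") >= pr - 1e-12, na.rm = TRUE))
  expect_error(permutationPvalues(otuTable(m), B = 0), "B must be")
})

test_that("permutation p-values are invariant to per-row affine rescaling", {
  withr::local_seed(33)
  m <- matrix(rexp(12 * 10), 12, 10,
              dimnames = list(sprintf("o%d", 1:12), sprintf("s%d", 1:10)))
  c1 <- permutationPvalues(otuTable(m), B = 50, seed = 9)
  m2 <- m * runif(12, 0.5, 4) + 0  # positive per-row scaling
  c2 <- permutationPvalues(otuTable(m2), B = 50, seed = 9)
  expect_equal(slot(c1, "r"), slot(c2, "r"), tolerance = 1e-12)
  expect_equal(slot(c1, "pRaw"), slot(c2, "pRaw"))
})

test_that("edge calling is monotone in alpha and rMin, and the build is reproducible", {
  withr::local_seed(55)
  spec <- syntheticSpec(nOtus = 20, depth = 5000, nSamples = 15,
                        blocks = list(list(otus = 1:4, rho = 0.9)))
  sim <- simulateOtuTable(spec, seed = 8)
  corr <- permutationPvalues(relativeAbundance(sim$table), B = 100, seed = 21)
  net1 <- buildNetwork(corr, alpha = 0.01)
  netLoose <- buildNetwork(corr, alpha = 0.05)
  netTight <- buildNetwork(corr, alpha = 0.001)
  netR <- buildNetwork(corr, alpha = 0.01, rMin = 0.8)
  keys <- function(net) pairKeys <- paste(networkEdges(net)$otu1,
                                          networkEdges(net)$otu2)
  expect_true(all(keys(net1) %in% keys(netLoose)))
  expect_true(all(keys(netTight) %in% keys(net1)))
  expect_true(all(keys(netR) %in% keys(net1)))

  # bit-reproducible given the seed
  corr2 <- permutationPvalues(relativeAbundance(sim$table), B = 100,
                              seed = 21)
  expect_identical(slot(corr, "pRaw"), slot(corr2, "pRaw"))
  expect_identical(networkEdges(buildNetwork(corr2, alpha = 0.01)),
                   networkEdges(net1))

  expect_error(buildNetwork(corr, alpha = 0), "alpha")
})

test_that("degenerate networks are handled", {
  # no significant pair -> empty network
  n <- 4
  ids <- sprintf("o%d", 1:n)
  r <- diag(n); dimnames(r) <- list(ids, ids)
  p1 <- matrix(1, n, n, dimnames = dimnames(r)); diag(p1) <- NA
  corr <- new("CorrelationResult", otuIds = ids, r = r, pRaw = p1,
              pAdj = p1, nPermutations = 100L, pseudocount = FALSE,
              zeroVariance = rep(FALSE, n), seed = NA_integer_)
  net <- buildNetwork(corr)
  expect_equal(networkMetrics(net)$nNodes, 0L)
  expect_equal(nrow(networkEdges(net)), 0L)
  expect_error(hubScores(net), "empty network")

  # exactly one significant pair -> 2 nodes, 1 edge, density 1
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1
  net1 <- networkFromAdjacency(A)
  m <- networkMetrics(net1)
  expect_equal(m$nNodes, 2L)
  expect_equal(m$nEdges, 1L)
  expect_equal(m$density, 1)
})

test_that("per-pair false-edge rate on null tables stays below 1.5x alpha", {
  spec <- presetSpec("mini")   # 100 independent OTUs, 20 samples
  sim <- simulateOtuTable(spec, seed = 303)
  corr <- permutationPvalues(relativeAbundance(sim$table), B = 200,
                             seed = 304)
  net <- buildNetwork(corr, alpha = 0.01)
  nPairs <- choose(100, 2)
  rate <- nrow(networkEdges(net)) / nPairs
  expect_lte(rate, 1.5 * 0.01)
})

test_that("hub scores match closed forms and a power-iteration oracle", {
  # complete graph: all scores 1
  K4 <- matrix(1, 4, 4) - diag(4)
  hsK <- hubScores(networkFromAdjacency(K4))
  expect_equal(unname(hsK$scores), rep(1, 4))

  # star K_{1,3}: center 1, leaves 1/sqrt(3)
  A <- matrix(0, 4, 4); A[1, 2:4] <- 1; A <- A + t(A)
  hs <- hubScores(networkFromAdjacency(A))
  expect_equal(unname(hs$scores[1]), 1)
  expect_equal(unname(hs$scores[2:4]), rep(1 / sqrt(3), 3),
               tolerance = 1e-6)
  expect_equal(hs$topHubs[1], "n01")

  # random graphs vs dense power iteration
  for (seed in c(1, 7, 19)) {
    A <- randomAdjacency(40, p = 0.15, seed = seed)
    keep <- rowSums(A) > 0
    A <- A[keep, keep]
    net <- networkFromAdjacency(A)
    hs <- hubScores(net, k = nrow(A))
    oracle <- powerIterationScores(A)
    names(oracle) <- sprintf("n%02d", seq_len(nrow(A)))
    expect_equal(hs$scores[names(oracle)], oracle, tolerance = 1e-8)
  }
})

test_that("global metrics match closed forms on K4, P4, K13", {
  K4 <- matrix(1, 4, 4) - diag(4)
  m <- networkMetrics(networkFromAdjacency(K4))
  expect_equal(m[c("density", "transitivity", "diameter",
                   "averagePathLength")],
               list(density = 1, transitivity = 1, diameter = 1,
                    averagePathLength = 1))

  P4 <- matrix(0, 4, 4)
  P4[1, 2] <- P4[2, 3] <- P4[3, 4] <- 1
  P4 <- P4 + t(P4)
  m <- networkMetrics(networkFromAdjacency(P4))
  expect_equal(m$density, 0.5)
  expect_equal(m$transitivity, 0)
  expect_equal(m$diameter, 3)
  expect_equal(m$averagePathLength, 10 / 6)

  K13 <- matrix(0, 4, 4); K13[1, 2:4] <- 1; K13 <- K13 + t(K13)
  m <- networkMetrics(networkFromAdjacency(K13))
  expect_equal(m$density, 0.5)
  expect_equal(m$transitivity, 0)
  expect_equal(m$diameter, 2)
  expect_equal(m$averagePathLength, (3 * 1 + 3 * 2) / 6)
})

test_that("global metrics equal the Floyd-Warshall + triple-count oracle on random graphs", {
  for (seed in 1:10) {
    A <- randomAdjacency(30, p = 0.1, seed = seed * 13)
    keep <- rowSums(A) > 0
    A <- A[keep, keep, drop = FALSE]
    if (nrow(A) < 2) next
    got <- networkMetrics(networkFromAdjacency(A))
    want <- bruteMetrics(A)
    expect_equal(got$nNodes, want$nNodes)
    expect_equal(got$nEdges, want$nEdges)
    expect_equal(got$density, want$density)
    expect_equal(got$transitivity, want$transitivity)
    expect_equal(got$diameter, want$diameter)
    expect_equal(got$averagePathLength, want$averagePathLength)
  }
})

test_that("node composition tallies taxonomy fractions", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 3] <- 1; A <- A + t(A)
  net <- networkFromAdjacency(A, ids = c("x", "y", "z"))
  tax <- data.frame(phylum = c("Proteobacteria", "Proteobacteria"),
                    row.names = c("x", "y"))
  comp <- nodeComposition(net, tax)
  expect_equal(comp$fraction[comp$taxon == "Proteobacteria"], 2 / 3)
  expect_equal(comp$fraction[comp$taxon == "unclassified"], 1 / 3)
  expect_equal(sum(comp$fraction), 1)

  # random assignments vs a direct tally
  withr::local_seed(41)
  A <- randomAdjacency(15, p = 0.3, seed = 4)
  keep <- rowSums(A) > 0
  net <- networkFromAdjacency(A[keep, keep])
  nodes <- igraph::V(networkGraph(net))$name
  phyla <- sample(c("A", "B", "C"), length(nodes), replace = TRUE)
  tax <- data.frame(phylum = phyla, row.names = nodes)
  comp <- nodeComposition(net, tax)
  for (ph in unique(phyla))
    expect_equal(comp$fraction[comp$taxon == ph],
                 mean(phyla == ph))
})
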