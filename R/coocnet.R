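# Permutation-calibrated Pearson co-occurrence network: correlation matrix,
# row-permutation null, BH edge calling, hub scores, global graph metrics.

#' Pairwise Pearson correlation between OTUs
#'
#' Pearson correlation of every OTU pair across samples. OTUs with zero
#' variance across samples have no defined correlation; their rows/columns
#' are `NA` (the diagonal of defined OTUs is 1).
#'
#' @param table an [OtuTable-class] with at least 3 samples (correlations
#'   are typically computed on relative abundances; see [mergeDomains()]).
#' @return symmetric correlation matrix with OTU ids as dimnames.
#' @export
pearsonMatrix <- function(table) {
  stopifnot(is(table, "OtuTable"))
  m <- abundances(table)
  if (ncol(m) < 3L)
    stop("Pearson correlation requires at least 3 samples", call. = FALSE)
  r <- suppressWarnings(cor(t(m)))
  zv <- apply(m, 1L, sd) == 0
  r[zv, ] <- NA_real_
  r[, zv] <- NA_real_
  diag(r)[!zv] <- 1
  r
}

#' Permutation p-values for all pairwise OTU correlations
#'
#' Calibrates every pairwise Pearson coefficient against a permutation null
#' that destroys exactly the quantity being tested: in each of `B`
#' replicates, every OTU row's sample order is shuffled independently
#' (breaking all inter-OTU dependence while preserving each OTU's marginal
#' distribution) and the full correlation matrix is recomputed. The raw
#' p-value of pair (i, j) is the fraction of replicates with
#' \eqn{|r^{(b)}_{ij}| \ge |r_{ij}|}; zero is attainable, which keeps the
#' procedure sensitive at small `B` (with `pseudocount = TRUE` the
#' conservative \eqn{(count+1)/(B+1)} variant is used instead). The
#' Benjamini-Hochberg adjustment is applied across all testable pairs.
#'
#' @param table an [OtuTable-class] with at least 3 samples.
#' @param B number of table permutations (default 100).
#' @param seed integer seed, or `NULL`.
#' @param pseudocount logical; use the \eqn{(count+1)/(B+1)} convention.
#' @return A [CorrelationResult-class].
#' @seealso [buildNetwork()]
#' @export
permutationPvalues <- function(table, B = 100L, seed = NULL,
                               pseudocount = FALSE) {
  stopifnot(is(table, "OtuTable"))
  if (!is.numeric(B) || length(B) != 1L || B < 1)
    stop("B must be >= 1", call. = FALSE)
  B <- as.integer(B)
  m <- abundances(table)
  nOtu <- nrow(m)
  n <- ncol(m)
  if (n < 3L)
    stop("permutation test requires at least 3 samples", call. = FALSE)
  zv <- apply(m, 1L, sd) == 0
  r <- pearsonMatrix(table)
  absObs <- abs(r)

  counts <- matrix(0, nOtu, nOtu)
  withSeed(seed, {
    perm <- m
    for (b in seq_len(B)) {
      for (i in seq_len(nOtu)) perm[i, ] <- m[i, sample.int(n)]
      rb <- suppressWarnings(abs(cor(t(perm))))
      counts <- counts + (rb >= absObs)
    }
  })
  pRaw <- if (pseudocount) (counts + 1) / (B + 1) else counts / B
  pRaw[zv, ] <- NA_real_
  pRaw[, zv] <- NA_real_
  diag(pRaw) <- NA_real_

  pAdj <- matrix(NA_real_, nOtu, nOtu, dimnames = dimnames(r))
  ut <- upper.tri(pRaw)
  testable <- ut & !is.na(pRaw)
  pAdj[testable] <- bhAdjust(pRaw[testable])
  pAdj[lower.tri(pAdj)] <- t(pAdj)[lower.tri(pAdj)]

  new("CorrelationResult",
      otuIds = rownames(m), r = r, pRaw = pRaw, pAdj = pAdj,
      nPermutations = B, pseudocount = isTRUE(pseudocount),
      zeroVariance = zv,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "CorrelationResult", function(object) {
  nTest <- sum(!object@zeroVariance)
  cat(sprintf(
    "CorrelationResult: %d OTUs (%d testable), B = %d permutations%s\n",
    length(object@otuIds), nTest, object@nPermutations,
    if (object@pseudocount) " (pseudocount)" else ""))
  invisible(object)
})

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values: with p-values sorted ascending,
#' \eqn{adj_{(i)} = \min_{j \ge i} (p_{(j)} \cdot m / j)} capped at 1 and
#' mapped back to the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted p-values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))        # all 0.04
#' bhAdjust(c(0.005, 0.011, 0.02, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Build the co-occurrence network from calibrated correlations
#'
#' Retains an undirected edge between two OTUs when the BH-adjusted p-value
#' is at most `alpha` and \eqn{|r| \ge rMin}. Nodes are the OTUs incident to
#' at least one retained edge: isolated OTUs are excluded, matching the
#' convention that the network describes detected interactions. Hub scores
#' (top 20) and global metrics are computed at build time.
#'
#' @param corr a [CorrelationResult-class].
#' @param alpha significance threshold on adjusted p-values, in `(0, 1]`
#'   (default 0.01).
#' @param rMin minimum absolute correlation for an edge (default 0; the
#'   magnitude cutoff is exposed because "strong" is study-specific).
#' @return A [CoocNetwork-class].
#' @export
buildNetwork <- function(corr, alpha = 0.01, rMin = 0) {
  stopifnot(is(corr, "CorrelationResult"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(rMin) || length(rMin) != 1L || rMin < 0 || rMin > 1)
    stop("rMin must lie in [0, 1]", call. = FALSE)
  sel <- which(upper.tri(corr@pAdj) & !is.na(corr@pAdj) &
                 corr@pAdj <= alpha & abs(corr@r) >= rMin, arr.ind = TRUE)
  ids <- corr@otuIds
  edges <- data.frame(
    otu1 = ids[sel[, 1L]], otu2 = ids[sel[, 2L]],
    r = corr@r[sel], pRaw = corr@pRaw[sel], pAdj = corr@pAdj[sel],
    stringsAsFactors = FALSE)
  ord <- order(edges$otu1, edges$otu2)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  g <- if (nrow(edges)) {
    igraph::graph_from_data_frame(edges, directed = FALSE)
  } else igraph::make_empty_graph(0, directed = FALSE)
  net <- new("CoocNetwork", graph = g, edges = edges,
             alpha = alpha, rMin = rMin, metrics = list(),
             hubScores = numeric(0), topHubs = character(0))
  net@metrics <- computeGraphMetrics(g)
  if (nrow(edges)) {
    hs <- computeHubScores(g, k = 20L)
    net@hubScores <- hs$scores
    net@topHubs <- hs$topHubs
  }
  validObject(net)
  net
}

#' @rdname buildNetwork
#' @param x a [CoocNetwork-class].
#' @export
setMethod("networkEdges", "CoocNetwork", function(x) x@edges)

#' @rdname buildNetwork
#' @export
setMethod("networkGraph", "CoocNetwork", function(x) x@graph)

setMethod("show", "CoocNetwork", function(object) {
  m <- object@metrics
  cat(sprintf(
    "CoocNetwork: %d nodes, %d edges (alpha = %g, |r| >= %g)\n",
    m$nNodes, m$nEdges, object@alpha, object@rMin))
  if (m$nEdges > 0)
    cat(sprintf(
      "  density %.4g | transitivity %.4g | diameter %s | APL %.4g\n",
      m$density, m$transitivity, format(m$diameter), m$averagePathLength))
  invisible(object)
})

computeGraphMetrics <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0L)
    return(list(nNodes = 0L, nEdges = 0L, density = NA_real_,
                transitivity = NA_real_, diameter = NA_real_,
                averagePathLength = NA_real_))
  dens <- if (n >= 2L) 2 * m / (n * (n - 1)) else NA_real_
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- NA_real_  # no connected triples
  # within components: largest finite distance / mean over connected pairs
  diam <- igraph::diameter(g, directed = FALSE, unconnected = TRUE,
                           weights = NA)
  apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  list(nNodes = n, nEdges = m, density = dens, transitivity = trans,
       diameter = as.numeric(diam), averagePathLength = apl)
}

computeHubScores <- function(g, k = 20L) {
  # principal eigenvector of the (unweighted) adjacency matrix, max = 1;
  # on disconnected graphs the score concentrates on the dominant component
  sc <- igraph::eigen_centrality(g, directed = FALSE, weights = NA)$vector
  # snap solver jitter (~1e-16) so symmetric nodes tie exactly and the
  # id tie-break is deterministic across runs
  sc <- round(sc, 12)
  ord <- order(-sc, names(sc))
  sc <- sc[ord]
  list(scores = sc, topHubs = names(sc)[seq_len(min(k, length(sc)))])
}

#' Hub (keystone) scores of a co-occurrence network
#'
#' Hub centrality: the principal eigenvector of the network's adjacency
#' matrix, normalized so the maximum score is 1. The `k` highest-scoring
#' OTUs (descending score, ties broken by node id) are the candidate
#' keystone taxa.
#'
#' @param x a [CoocNetwork-class] with at least one edge.
#' @param k number of top hubs to report (default 20; all nodes if fewer).
#' @return list with `scores` (named numeric vector, sorted) and `topHubs`
#'   (character vector of length `min(k, nNodes)`).
#' @rdname hubScores
#' @export
setMethod("hubScores", "CoocNetwork", function(x, k = 20L) {
  if (igraph::ecount(x@graph) == 0L)
    stop("hub scores are undefined for an empty network", call. = FALSE)
  computeHubScores(x@graph, k = as.integer(k))
})

#' Global metrics of a co-occurrence network
#'
#' Number of nodes and edges, density \eqn{2m / (n(n-1))}, global
#' transitivity (3 x triangles / connected triples), diameter (largest
#' finite shortest-path length, i.e. within components) and average path
#' length (mean shortest-path length over connected unordered pairs;
#' disconnected pairs are excluded). Undefined quantities (e.g. on an empty
#' network, or transitivity with no connected triples) are returned as `NA`.
#'
#' @param x a [CoocNetwork-class].
#' @return list with `nNodes`, `nEdges`, `density`, `transitivity`,
#'   `diameter`, `averagePathLength`.
#' @rdname networkMetrics
#' @export
setMethod("networkMetrics", "CoocNetwork", function(x) x@metrics)

#' Taxonomic composition of network nodes
#'
#' Fraction of network nodes per taxon at a given rank. Nodes absent from
#' the taxonomy table (or with an empty rank entry) are reported as
#' `"unclassified"`.
#'
#' @param net a [CoocNetwork-class] with at least one node.
#' @param taxonomy data.frame from [readTaxonomy()] (OTU ids as row names).
#' @param rank taxonomy column to summarize at (default `"phylum"`).
#' @return data.frame with columns `taxon` and `fraction` (sums to 1),
#'   sorted by decreasing fraction.
#' @export
nodeComposition <- function(net, taxonomy, rank = "phylum") {
  stopifnot(is(net, "CoocNetwork"))
  nodes <- igraph::V(net@graph)$name
  if (!length(nodes))
    stop("network has no nodes", call. = FALSE)
  lab <- rep("unclassified", length(nodes))
  if (rank %in% colnames(taxonomy)) {
    hit <- nodes %in% rownames(taxonomy)
    v <- as.character(taxonomy[nodes[hit], rank])
    v[is.na(v) | v == ""] <- "unclassified"
    lab[hit] <- v
  }
  tab <- sort(table(lab), decreasing = TRUE)
  data.frame(taxon = names(tab),
             fraction = as.numeric(tab) / length(nodes),
             stringsAsFactors = FALSE)
}
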