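setOldClass("igraph")

#' OtuTable: an OTU-by-sample abundance matrix
#'
#' Container for an OTU table: a numeric matrix with OTUs as rows and
#' samples as columns, plus a flag saying whether the values are raw
#' sequence counts or per-sample relative abundances. Row names are OTU
#' identifiers and column names are sample identifiers; both must be unique.
#'
#' For a relative table every non-zero sample column must sum to the same
#' constant (1 for a plain relative table; after [mergeDomains()] of k
#' marker datasets the constant is k, because each marker is normalized
#' independently before concatenation). All-zero columns are permitted.
#'
#' @slot counts numeric matrix, OTUs x samples, non-negative, with unique
#'   dimnames.
#' @slot relative logical flag; `TRUE` if values are relative abundances.
#'
#' @seealso [otuTable()], [readOtuTable()], [relativeAbundance()],
#'   [mergeDomains()]
#' @export
setClass("OtuTable",
         slots = c(counts = "matrix", relative = "logical"))

setValidity("OtuTable", function(object) {
  m <- object@counts
  msgs <- character()
  if (!is.numeric(m))
    msgs <- c(msgs, "counts must be a numeric matrix")
  if (length(object@relative) != 1L || is.na(object@relative))
    msgs <- c(msgs, "relative must be TRUE or FALSE")
  if (is.null(colnames(m)) || anyNA(colnames(m)) || any(colnames(m) == ""))
    msgs <- c(msgs, "sample ids (column names) must be present and non-empty")
  if (nrow(m) > 0L &&
      (is.null(rownames(m)) || anyNA(rownames(m)) || any(rownames(m) == "")))
    msgs <- c(msgs, "OTU ids (row names) must be present and non-empty")
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
    msgs <- c(msgs, sprintf("duplicated OTU id: %s",
                            rownames(m)[duplicated(rownames(m))][1L]))
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    msgs <- c(msgs, sprintf("duplicated sample id: %s",
                            colnames(m)[duplicated(colnames(m))][1L]))
  if (is.numeric(m) && length(m)) {
    if (anyNA(m) || any(!is.finite(m)))
      msgs <- c(msgs, "counts must be finite and non-missing")
    else if (any(m < 0))
      msgs <- c(msgs, "counts must be non-negative")
    else if (isTRUE(object@relative) && ncol(m) > 0L) {
      cs <- colSums(m)
      nz <- cs[cs > 0]
      if (length(nz) && (max(nz) - min(nz)) > 1e-9 * max(nz))
        msgs <- c(msgs,
                  "relative table: non-zero sample columns must share a common sum")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CorrelationResult: permutation-calibrated pairwise Pearson correlations
#'
#' Result of [permutationPvalues()]: the observed OTU-by-OTU Pearson
#' correlation matrix together with permutation p-values and their
#' Benjamini-Hochberg adjustment. OTUs with zero variance across samples
#' cannot be tested; their rows/columns are `NA` (flagged in
#' `zeroVariance`).
#'
#' @slot otuIds character vector of OTU identifiers.
#' @slot r symmetric matrix of Pearson coefficients (diagonal 1, `NA` where
#'   undefined).
#' @slot pRaw symmetric matrix of permutation p-values (diagonal `NA`).
#' @slot pAdj symmetric matrix of BH-adjusted p-values.
#' @slot nPermutations integer, number of row-permutation replicates B.
#' @slot pseudocount logical; `TRUE` if p = (count+1)/(B+1) was used.
#' @slot zeroVariance logical vector flagging untestable OTUs.
#' @slot seed integer seed used (NA if none supplied).
#'
#' @seealso [permutationPvalues()], [buildNetwork()]
#' @export
setClass("CorrelationResult",
         slots = c(otuIds = "character", r = "matrix", pRaw = "matrix",
                   pAdj = "matrix", nPermutations = "integer",
                   pseudocount = "logical", zeroVariance = "logical",
                   seed = "integer"))

setValidity("CorrelationResult", function(object) {
  n <- length(object@otuIds)
  msgs <- character()
  for (nm in c("r", "pRaw", "pAdj")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n)))
      msgs <- c(msgs, sprintf("%s must be %d x %d", nm, n, n))
    else if (any(abs(m - t(m)) > 1e-12, na.rm = TRUE))
      msgs <- c(msgs, sprintf("%s must be symmetric", nm))
  }
  if (any(abs(object@r) > 1 + 1e-12, na.rm = TRUE))
    msgs <- c(msgs, "|r| must be <= 1")
  if (any(object@pRaw < 0 | object@pRaw > 1, na.rm = TRUE))
    msgs <- c(msgs, "pRaw must lie in [0, 1]")
  if (any(object@pAdj < object@pRaw - 1e-12, na.rm = TRUE))
    msgs <- c(msgs, "pAdj must be >= pRaw element-wise")
  if (object@nPermutations < 1L)
    msgs <- c(msgs, "nPermutations must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' CoocNetwork: a significant co-occurrence network over OTUs
#'
#' Undirected simple graph whose nodes are OTUs incident to at least one
#' retained edge and whose edges are OTU pairs passing the
#' Benjamini-Hochberg significance threshold (and optional |r| cutoff).
#' Global metrics and hub scores are computed at build time and retrievable
#' with [networkMetrics()] and [hubScores()].
#'
#' @slot graph the underlying [igraph::igraph] object.
#' @slot edges data.frame with columns otu1, otu2, r, pRaw, pAdj.
#' @slot alpha numeric, BH-adjusted significance threshold used.
#' @slot rMin numeric, minimum |r| required for an edge.
#' @slot metrics list of global metrics (nNodes, nEdges, density,
#'   transitivity, diameter, averagePathLength).
#' @slot hubScores named numeric vector, adjacency principal-eigenvector
#'   scores normalized to max 1 (empty for an empty network).
#' @slot topHubs character vector of the top-scoring nodes (descending
#'   score, ties broken by node id).
#'
#' @seealso [buildNetwork()], [hubScores()], [networkMetrics()],
#'   [nodeComposition()]
#' @export
setClass("CoocNetwork",
         slots = c(graph = "igraph", edges = "data.frame", alpha = "numeric",
                   rMin = "numeric", metrics = "list", hubScores = "numeric",
                   topHubs = "character"))

setValidity("CoocNetwork", function(object) {
  msgs <- character()
  ed <- object@edges
  need <- c("otu1", "otu2", "r", "pRaw", "pAdj")
  if (!all(need %in% names(ed)))
    msgs <- c(msgs, "edges must have columns otu1, otu2, r, pRaw, pAdj")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must lie in (0, 1]")
  if (nrow(ed) > 0L && length(object@hubScores) &&
      abs(max(object@hubScores) - 1) > 1e-8)
    msgs <- c(msgs, "maximum hub score must be 1 for a non-empty network")
  if (length(msgs)) msgs else TRUE
})
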