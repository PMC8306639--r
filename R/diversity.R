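#' Alpha-diversity indices
#'
#' Per-sample indices for OTU abundance vectors:
#' \describe{
#'   \item{`chao1(x)`}{bias-corrected Chao1 richness,
#'     \eqn{S_{obs} + F_1(F_1-1) / (2(F_2+1))}, where \eqn{F_1}/\eqn{F_2}
#'     are the numbers of singletons and doubletons. The bias-corrected form
#'     is used uniformly, so \eqn{F_2 = 0} needs no special case. Requires
#'     integer counts.}
#'   \item{`shannonIndex(x)`}{Shannon entropy \eqn{H = -\sum p_i \ln p_i}
#'     in nats (natural log), over positive entries.}
#'   \item{`simpsonIndex(x)`}{Gini-Simpson index \eqn{1 - \sum p_i^2}.}
#'   \item{`evennessIndex(x)`}{Hill-number evenness \eqn{e^H / S} with
#'     \eqn{S} the number of positive entries; equals 1 for a perfectly
#'     even community.}
#' }
#' `shannonIndex`, `simpsonIndex` and `evennessIndex` accept counts or
#' proportions (they are scale-invariant); `chao1` is only defined on
#' counts.
#'
#' @param x non-negative numeric vector of abundances with at least one
#'   positive entry (integer counts for `chao1`).
#' @return A single number.
#' @examples
#' chao1(c(rep(5, 6), 1, 1, 1, 1, 2, 2))       # S=12, F1=4, F2=2 -> 14
#' shannonIndex(c(1, 1, 1, 1))                 # log(4)
#' simpsonIndex(c(0.5, 0.25, 0.25))            # 0.625
#' evennessIndex(c(10, 10, 10))                # 1
#' @name alpha-indices
NULL

checkAbundanceVector <- function(x) {
  if (!is.numeric(x) || !length(x) || anyNA(x) || any(x < 0))
    stop("abundances must be a non-negative numeric vector", call. = FALSE)
  if (sum(x) == 0)
    stop("all-zero abundance vector", call. = FALSE)
}

#' @rdname alpha-indices
#' @export
chao1 <- function(x) {
  checkAbundanceVector(x)
  if (!isWholeNumber(x))
    stop("Chao1 requires integer counts", call. = FALSE)
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname alpha-indices
#' @export
shannonIndex <- function(x) {
  checkAbundanceVector(x)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' @rdname alpha-indices
#' @export
simpsonIndex <- function(x) {
  checkAbundanceVector(x)
  p <- x[x > 0] / sum(x)
  1 - sum(p^2)
}

#' @rdname alpha-indices
#' @export
evennessIndex <- function(x) {
  checkAbundanceVector(x)
  evennessFromShannon(shannonIndex(x), sum(x > 0))
}

#' Hill evenness from a Shannon value and a richness
#'
#' The evenness definition used throughout the package: \eqn{e^H / S}, the
#' ratio of the Shannon effective number of taxa (Hill number of order 1) to
#' the taxa count. This form, unlike Pielou's \eqn{H / \ln S}, is consistent
#' with published soil-community summary tables in which communities of
#' ~1,150 taxa with \eqn{H \approx 6.2} nats are reported with evenness
#' 0.4-0.5.
#'
#' @param shannon Shannon entropy in nats.
#' @param richness number of taxa (may be a non-integer mean over
#'   replicates).
#' @return \eqn{e^{shannon} / richness}.
#' @examples
#' evennessFromShannon(6.2, 1138.7)   # ~0.43
#' @export
evennessFromShannon <- function(shannon, richness) {
  if (any(richness <= 0)) stop("richness must be positive", call. = FALSE)
  exp(shannon) / richness
}

#' Per-sample alpha-diversity table
#'
#' Computes, for every sample, the number of observed OTUs (count > 0),
#' Chao1 (only for count tables; `NA` on relative data), Shannon (nats),
#' Gini-Simpson and Hill evenness.
#'
#' @param table an [OtuTable-class].
#' @return data.frame with one row per sample and columns `sample_id`,
#'   `taxa_number`, `chao1`, `shannon`, `simpson`, `evenness`.
#' @seealso [alphaDiversitySummary()]
#' @export
alphaDiversity <- function(table) {
  stopifnot(is(table, "OtuTable"))
  m <- abundances(table)
  isCounts <- !isRelative(table) && isWholeNumber(m)
  rows <- lapply(colnames(m), function(s) {
    x <- m[, s]
    data.frame(sample_id = s,
               taxa_number = sum(x > 0),
               chao1 = if (isCounts) chao1(x) else NA_real_,
               shannon = shannonIndex(x),
               simpson = simpsonIndex(x),
               evenness = evennessIndex(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Alpha diversity summarized by condition
#'
#' Mean and standard deviation of each alpha index over the replicate
#' samples of every condition, where a condition is a combination of the
#' `groupBy` metadata factors.
#'
#' @param table an [OtuTable-class].
#' @param metadata data.frame of sample metadata (row names = sample ids),
#'   e.g. from [readSampleMetadata()].
#' @param groupBy character vector of metadata column names defining the
#'   conditions.
#' @return data.frame with one row per condition x index, columns
#'   `condition`, `index`, `mean`, `sd`, `n`.
#' @export
alphaDiversitySummary <- function(table, metadata,
                                  groupBy = c("soil", "plant", "treatment")) {
  stopifnot(is(table, "OtuTable"), is.data.frame(metadata))
  missing <- setdiff(sampleIds(table), rownames(metadata))
  if (length(missing))
    stop(sprintf("samples missing from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- setdiff(groupBy, colnames(metadata))
  if (length(bad))
    stop(sprintf("unknown metadata factor: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  alpha <- alphaDiversity(table)
  grp <- interaction(metadata[alpha$sample_id, groupBy, drop = FALSE],
                     sep = ".", drop = TRUE)
  idx <- c("taxa_number", "chao1", "shannon", "simpson", "evenness")
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- alpha[grp == g, , drop = FALSE]
    do.call(rbind, lapply(idx, function(i) {
      data.frame(condition = g, index = i,
                 mean = mean(sel[[i]]), sd = sd(sel[[i]]),
                 n = nrow(sel), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{D(a,b) = \sum_i |x_{ia} - x_{ib}| / \sum_i (x_{ia} + x_{ib})}
#' between every pair of samples. Values lie in `[0, 1]`; the matrix is
#' symmetric with a zero diagonal. A pair of all-zero samples is assigned
#' distance 0 by convention. Bray-Curtis is a semimetric: the triangle
#' inequality is not guaranteed.
#'
#' @param table an [OtuTable-class] with at least two samples.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
brayCurtis <- function(table) {
  stopifnot(is(table, "OtuTable"))
  m <- abundances(table)
  n <- ncol(m)
  if (n < 2L)
    stop("Bray-Curtis requires at least two samples", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      den <- sum(m[, i] + m[, j])
      d <- if (den == 0) 0 else sum(abs(m[, i] - m[, j])) / den
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Presence sets of OTUs per condition
#'
#' For each condition (combination of `groupBy` factors), the set of OTUs
#' considered present: detected (count > 0) in at least one replicate
#' (`mode = "any"`, default) or in all replicates (`mode = "all"`).
#'
#' @param table an [OtuTable-class].
#' @param metadata sample metadata data.frame (row names = sample ids).
#' @param groupBy character vector of metadata columns defining conditions.
#' @param mode `"any"` or `"all"`.
#' @return named list of character vectors of OTU ids.
#' @seealso [vennPartition()]
#' @export
presenceSets <- function(table, metadata,
                         groupBy = c("soil", "plant", "treatment"),
                         mode = c("any", "all")) {
  stopifnot(is(table, "OtuTable"), is.data.frame(metadata))
  mode <- match.arg(mode)
  missing <- setdiff(sampleIds(table), rownames(metadata))
  if (length(missing))
    stop(sprintf("samples missing from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  m <- abundances(table)
  grp <- interaction(metadata[colnames(m), groupBy, drop = FALSE],
                     sep = ".", drop = TRUE)
  sets <- lapply(levels(grp), function(g) {
    sub <- m[, grp == g, drop = FALSE] > 0
    hit <- if (mode == "any") rowSums(sub) > 0 else rowSums(sub) == ncol(sub)
    rownames(m)[hit]
  })
  names(sets) <- levels(grp)
  sets
}

#' Venn partition of 2-3 OTU presence sets
#'
#' Exact set-algebra partition of two or three named OTU-id sets into
#' disjoint regions: OTUs specific to each group, shared by each pair (for
#' three groups) and shared by all. Region names join the group names with
#' `&`.
#'
#' @param sets named list of 2 or 3 character vectors (OTU ids).
#' @return list with elements `regions` (named list of id vectors) and
#'   `sizes` (named integer vector). Regions are disjoint and their union is
#'   the union of the input sets.
#' @examples
#' vennPartition(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
#' @export
vennPartition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop("vennPartition supports 2 or 3 groups", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nms <- names(sets)
  k <- length(sets)
  regions <- list()
  # iterate over non-empty subsets of groups, largest first
  combos <- unlist(lapply(seq(k, 1L), function(sz)
    utils::combn(seq_len(k), sz, simplify = FALSE)), recursive = FALSE)
  for (combo in combos) {
    inAll <- Reduce(intersect, sets[combo])
    others <- setdiff(seq_len(k), combo)
    excl <- if (length(others)) setdiff(inAll, Reduce(union, sets[others]))
            else inAll
    regions[[paste(nms[combo], collapse = "&")]] <- excl
  }
  list(regions = regions,
       sizes = vapply(regions, length, integer(1)))
}
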