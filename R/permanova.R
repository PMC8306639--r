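#' Gower-center a distance matrix
#'
#' Computes \eqn{G = -\frac{1}{2} J A J} with \eqn{A_{ij} = D_{ij}^2} and
#' \eqn{J = I - \mathbf{1}\mathbf{1}^T / n}. `G` is symmetric with zero row
#' sums, and its trace equals the total sum of squares
#' \eqn{\frac{1}{n}\sum_{i<j} D_{ij}^2} that PERMANOVA partitions.
#'
#' @param D symmetric distance matrix (zero diagonal, non-negative) or a
#'   [stats::dist] object.
#' @return The doubly-centered matrix `G`.
#' @export
gowerCenter <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop("D must be a symmetric distance matrix", call. = FALSE)
  if (any(abs(diag(D)) > 1e-12))
    stop("D must have a zero diagonal", call. = FALSE)
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  sweep(sweep(A, 1, rm), 2, rm) + mean(A)
}

# ranks and orthonormal bases of the cumulative design matrices
cumulativeBases <- function(metadata, termLabels) {
  vars <- unique(unlist(strsplit(termLabels, ":", fixed = TRUE)))
  missing <- setdiff(vars, colnames(metadata))
  if (length(missing))
    stop(sprintf("unknown factor in formula: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  md <- metadata[, vars, drop = FALSE]
  for (v in vars) if (!is.numeric(md[[v]])) md[[v]] <- factor(md[[v]])
  # main effects must precede their interactions
  for (i in seq_along(termLabels)) {
    parts <- strsplit(termLabels[i], ":", fixed = TRUE)[[1L]]
    if (length(parts) > 1L) {
      earlier <- termLabels[seq_len(i - 1L)]
      absent <- setdiff(parts, earlier)
      if (length(absent))
        stop(sprintf(
          "main effect(s) %s must precede the interaction '%s'",
          paste(absent, collapse = ", "), termLabels[i]), call. = FALSE)
    }
  }
  n <- nrow(md)
  bases <- vector("list", length(termLabels))
  prevRank <- 1L  # intercept
  X <- model.matrix(~1, data = md)
  for (i in seq_along(termLabels)) {
    f <- reformulate(termLabels[seq_len(i)])
    X <- model.matrix(f, data = md)
    qrX <- qr(X)
    rank <- qrX$rank
    if (rank - prevRank < 1L)
      stop(sprintf("term '%s' is aliased with earlier terms (rank-deficient design)",
                   termLabels[i]), call. = FALSE)
    bases[[i]] <- list(Q = qr.Q(qrX)[, seq_len(rank), drop = FALSE],
                       df = rank - prevRank)
    prevRank <- rank
  }
  list(bases = bases, modelDf = prevRank - 1L)
}

# sequential sums of squares of G given orthonormal bases of the cumulative
# designs: SS_k = tr(H_k G) - tr(H_{k-1} G); tr(H G) = sum(Q * (G Q)).
sequentialSS <- function(G, bases) {
  tr <- vapply(bases, function(b) sum(b$Q * (G %*% b$Q)), numeric(1))
  diff(c(0, tr))
}

#' Permutation-based multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix among an ordered
#' list of design terms using sequential (Type-I) sums of squares computed
#' from projection matrices of the cumulative designs on the Gower-centered
#' matrix. Significance of each pseudo-F is assessed by unrestricted
#' permutation of sample labels, with the observed statistic counted as one
#' permutation: \eqn{p = (1 + \#\{F^{(b)} \ge F\}) / (1 + n_{perm})}, so the
#' smallest attainable p-value is \eqn{1/(n_{perm}+1)} (0.001 at 999
#' permutations).
#'
#' @param D distance matrix (symmetric, zero diagonal) with sample ids as
#'   dimnames, e.g. from [brayCurtis()], or a [stats::dist].
#' @param metadata data.frame of sample factors, row names = sample ids.
#' @param formula model formula such as
#'   `~ plant + treatment + soil + plant:soil`, or a character vector of
#'   term labels in the desired order. Main effects must precede their
#'   interactions; terms are fitted strictly in the order given.
#' @param nPerm number of permutations (default 999; 0 skips the test and
#'   returns `NA` p-values).
#' @param seed integer seed for the permutations, or `NULL`.
#' @return data.frame of class `c("permanovaTable", "data.frame")` with one
#'   row per term plus `Residual` and `Total`, columns `Df`, `SumOfSqs`,
#'   `R2`, `F`, `Pr(>F)`; attributes `nPermutations` and `seed`.
#' @examples
#' md <- data.frame(grp = rep(c("a", "b"), each = 4),
#'                  row.names = paste0("s", 1:8))
#' x <- c(1, 2, 3, 2, 6, 7, 8, 7)
#' D <- as.matrix(dist(x)); dimnames(D) <- list(rownames(md), rownames(md))
#' permanova(D, md, ~ grp, nPerm = 199, seed = 1)
#' @export
permanova <- function(D, metadata, formula, nPerm = 999L, seed = NULL) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D)
  ids <- rownames(D)
  if (is.null(ids))
    stop("D must carry sample ids as dimnames", call. = FALSE)
  if (!all(ids %in% rownames(metadata)))
    stop(sprintf("samples missing from metadata: %s",
                 paste(setdiff(ids, rownames(metadata)), collapse = ", ")),
         call. = FALSE)
  metadata <- metadata[ids, , drop = FALSE]
  termLabels <- if (inherits(formula, "formula")) {
    attr(terms(formula, keep.order = TRUE), "term.labels")
  } else as.character(formula)
  if (!length(termLabels)) stop("empty model formula", call. = FALSE)
  if (!is.numeric(nPerm) || length(nPerm) != 1L || nPerm < 0)
    stop("nPerm must be a non-negative integer", call. = FALSE)

  n <- nrow(D)
  cb <- cumulativeBases(metadata, termLabels)
  if (n < cb$modelDf + 2L)
    stop("not enough samples for the requested model", call. = FALSE)
  G <- gowerCenter(D)
  ssTotal <- sum(diag(G))
  ss <- sequentialSS(G, cb$bases)
  df <- vapply(cb$bases, `[[`, integer(1), "df")
  dfRes <- n - 1L - sum(df)
  ssRes <- ssTotal - sum(ss)
  Fobs <- (ss / df) / (ssRes / dfRes)

  pvals <- rep(NA_real_, length(ss))
  if (nPerm >= 1) {
    exceed <- integer(length(ss))
    withSeed(seed, {
      for (b in seq_len(nPerm)) {
        p <- sample.int(n)
        Gp <- G[p, p]
        ssb <- sequentialSS(Gp, cb$bases)
        ssResB <- ssTotal - sum(ssb)
        Fb <- (ssb / df) / (ssResB / dfRes)
        exceed <- exceed + (Fb >= Fobs)
      }
    })
    pvals <- (1 + exceed) / (1 + nPerm)
  }

  out <- data.frame(
    Df = c(df, dfRes, n - 1L),
    SumOfSqs = c(ss, ssRes, ssTotal),
    R2 = c(ss, ssRes, ssTotal) / ssTotal,
    F = c(Fobs, NA, NA),
    `Pr(>F)` = c(pvals, NA, NA),
    row.names = c(termLabels, "Residual", "Total"),
    check.names = FALSE)
  attr(out, "nPermutations") <- as.integer(nPerm)
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(out) <- c("permanovaTable", "data.frame")
  out
}

#' @export
print.permanovaTable <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations)\n",
              attr(x, "nPermutations")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
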