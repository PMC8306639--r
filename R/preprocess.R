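# Table-level denoising: negative-control OTU removal, relative-abundance
# filtering, rarefaction. Applied in that order by the pipeline.

filterReport <- function(before, after, removedControl, removedAbundance,
                         thresholdFraction, totalSequences) {
  stopifnot(before == after + removedControl + removedAbundance)
  list(nOtusBefore = before, nOtusAfter = after,
       nRemovedControl = removedControl,
       nRemovedAbundance = removedAbundance,
       thresholdFraction = thresholdFraction,
       totalSequences = totalSequences)
}

#' Remove OTUs detected in a negative-control sample
#'
#' Every OTU with a non-zero count in the control column is discarded (such
#' OTUs are treated as ambient/reagent contamination), and the control
#' column itself is dropped from the output.
#'
#' @param table an [OtuTable-class] of counts.
#' @param controlSampleId id of the negative-control sample.
#' @return list with elements `table` (filtered [OtuTable-class]) and
#'   `report` (filter report: counts before/after and removals).
#' @export
removeControlOtus <- function(table, controlSampleId) {
  stopifnot(is(table, "OtuTable"))
  m <- abundances(table)
  if (!controlSampleId %in% colnames(m))
    stop(sprintf("unknown control sample: %s", controlSampleId),
         call. = FALSE)
  inControl <- m[, controlSampleId] > 0
  keep <- !inControl
  out <- m[keep, setdiff(colnames(m), controlSampleId), drop = FALSE]
  if (!any(keep))
    warning("all OTUs were detected in the control sample; table is empty")
  list(table = otuTable(out, relative = isRelative(table)),
       report = filterReport(nrow(m), sum(keep), sum(inControl), 0L,
                             NA_real_, sum(m)))
}

#' Filter low-abundance OTUs
#'
#' Keeps OTUs whose total count is at least `thresholdFraction` of the grand
#' total of the table (all samples pooled); the comparison is inclusive
#' ("at least"). With the default threshold of 5e-5 (0.005%), a table with
#' 200,000 total sequences keeps OTUs with row sums >= 10. A threshold of 0
#' keeps every row, including all-zero rows (0 >= 0).
#'
#' @param table an [OtuTable-class] of counts (relative tables are
#'   rejected: the rule is defined on sequence counts).
#' @param thresholdFraction proportion in `[0, 1)`; default `5e-5`.
#' @return list with elements `table` and `report` (the report's
#'   `totalSequences` is the pre-filter grand total).
#' @export
filterLowAbundance <- function(table, thresholdFraction = 5e-5) {
  stopifnot(is(table, "OtuTable"))
  if (isRelative(table))
    stop("abundance filtering is defined on sequence counts, not relative abundances",
         call. = FALSE)
  if (!is.numeric(thresholdFraction) || length(thresholdFraction) != 1L ||
      thresholdFraction < 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in [0, 1)", call. = FALSE)
  m <- abundances(table)
  total <- sum(m)
  keep <- rowSums(m) >= thresholdFraction * total
  list(table = otuTable(m[keep, , drop = FALSE], relative = FALSE),
       report = filterReport(nrow(m), sum(keep), 0L, sum(!keep),
                             thresholdFraction, total))
}

#' Rarefy an OTU table to a fixed depth
#'
#' Each sample is randomly resampled down to `depth` sequences without
#' replacement (a multivariate hypergeometric draw from that sample's count
#' vector); a single draw is performed per sample. Output column sums equal
#' `depth` exactly and no OTU count can exceed its input count. The draw is
#' deterministic given `seed`.
#'
#' @param table an [OtuTable-class] of integer counts.
#' @param depth target number of sequences per sample; every sample must
#'   have a column sum of at least `depth` (drop shallower samples first).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A rarefied [OtuTable-class].
#' @export
rarefyTable <- function(table, depth, seed = NULL) {
  stopifnot(is(table, "OtuTable"))
  if (isRelative(table))
    stop("rarefaction requires integer counts", call. = FALSE)
  m <- abundances(table)
  if (!isWholeNumber(m))
    stop("rarefaction requires integer counts", call. = FALSE)
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0 ||
      depth != round(depth))
    stop("depth must be a positive integer", call. = FALSE)
  cs <- colSums(m)
  shallow <- colnames(m)[cs < depth]
  if (length(shallow))
    stop(sprintf("samples with fewer than %d sequences: %s",
                 as.integer(depth), paste(shallow, collapse = ", ")),
         call. = FALSE)
  out <- withSeed(seed, {
    res <- m
    for (j in seq_len(ncol(m))) {
      if (cs[j] == depth) next  # already at depth: no-op draw
      v <- as.integer(round(m[, j]))
      pool <- rep.int(seq_along(v), v)
      take <- sample(pool, depth)
      res[, j] <- tabulate(take, nbins = length(v))
    }
    res
  })
  otuTable(out, relative = FALSE)
}
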