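#' Construct an OtuTable
#'
#' @param counts numeric matrix (or coercible) with OTUs as rows and samples
#'   as columns; row names are OTU ids, column names sample ids.
#' @param relative logical; `TRUE` if `counts` holds per-sample relative
#'   abundances rather than raw sequence counts.
#'
#' @return A validated [OtuTable-class] object.
#' @examples
#' m <- matrix(c(5, 0, 3, 2, 1, 9), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' otuTable(m)
#' @export
otuTable <- function(counts, relative = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("OtuTable", counts = counts, relative = isTRUE(relative))
}

#' Accessors for OtuTable objects
#'
#' `otuIds()` and `sampleIds()` return the row/column identifiers,
#' `abundances()` the numeric matrix, `isRelative()` the relative-abundance
#' flag, and `nOtus()`/`nSamples()` the dimensions.
#'
#' @param x an [OtuTable-class].
#' @return See individual descriptions.
#' @name OtuTable-accessors
NULL

#' @rdname OtuTable-accessors
#' @export
setMethod("otuIds", "OtuTable", function(x) rownames(x@counts))

#' @rdname OtuTable-accessors
#' @export
setMethod("sampleIds", "OtuTable", function(x) colnames(x@counts))

#' @rdname OtuTable-accessors
#' @export
setMethod("abundances", "OtuTable", function(x) x@counts)

#' @rdname OtuTable-accessors
#' @export
setMethod("isRelative", "OtuTable", function(x) x@relative)

#' @rdname OtuTable-accessors
#' @export
setMethod("nOtus", "OtuTable", function(x) nrow(x@counts))

#' @rdname OtuTable-accessors
#' @export
setMethod("nSamples", "OtuTable", function(x) ncol(x@counts))

setMethod("show", "OtuTable", function(object) {
  cat(sprintf("OtuTable: %d OTUs x %d samples (%s)\n",
              nOtus(object), nSamples(object),
              if (isRelative(object)) "relative abundances" else "counts"))
  if (nSamples(object) > 0L && nOtus(object) > 0L) {
    cs <- colSums(object@counts)
    cat(sprintf("  column sums: min %.6g / max %.6g\n", min(cs), max(cs)))
  }
  invisible(object)
})

#' Convert an OtuTable to per-sample relative abundances
#'
#' Each sample column is divided by its sum; all-zero columns are left at
#' zero. The result is flagged `relative = TRUE`.
#'
#' @param table an [OtuTable-class].
#' @return An [OtuTable-class] of relative abundances.
#' @export
relativeAbundance <- function(table) {
  stopifnot(is(table, "OtuTable"))
  m <- table@counts
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cs[nz], "/")
  otuTable(m, relative = TRUE)
}

#' Merge OTU tables from different marker datasets into one table
#'
#' Combines tables (e.g. a 16S prokaryotic table and an ITS fungal table)
#' that cover the same samples but disjoint OTU sets. Because each marker
#' dataset is typically rarefied to its own depth, raw-count concatenation
#' would encode sequencing depth rather than biology: each input is first
#' converted to per-sample relative abundance independently, then the rows
#' are concatenated. Consequently each sample column of the merged table
#' sums to the number of input tables; pairwise Pearson correlation
#' downstream is unaffected by this constant.
#'
#' Samples are aligned strictly by sample id; the output uses the first
#' table's sample order.
#'
#' @param tables list of [OtuTable-class] objects sharing an identical
#'   sample id set, with pairwise-disjoint OTU ids.
#' @return A merged relative [OtuTable-class] with
#'   `sum(row counts of inputs)` rows.
#' @examples
#' a <- otuTable(matrix(c(2, 2, 30, 10), 2,
#'               dimnames = list(c("p1", "p2"), c("s1", "s2"))))
#' b <- otuTable(matrix(c(4, 6, 1, 0), 2,
#'               dimnames = list(c("f1", "f2"), c("s1", "s2"))))
#' mergeDomains(list(a, b))
#' @export
mergeDomains <- function(tables) {
  if (!is.list(tables) || !length(tables) ||
      !all(vapply(tables, is, logical(1), "OtuTable")))
    stop("'tables' must be a non-empty list of OtuTable objects", call. = FALSE)
  ref <- sampleIds(tables[[1L]])
  for (i in seq_along(tables)) {
    ids <- sampleIds(tables[[i]])
    missing <- setdiff(ref, ids)
    extra <- setdiff(ids, ref)
    if (length(missing) || length(extra))
      stop(sprintf(
        "sample sets differ between table 1 and table %d (missing: %s; extra: %s)",
        i,
        if (length(missing)) paste(missing, collapse = ", ") else "none",
        if (length(extra)) paste(extra, collapse = ", ") else "none"),
        call. = FALSE)
  }
  allOtus <- unlist(lapply(tables, otuIds))
  if (anyDuplicated(allOtus))
    stop(sprintf("OTU id collision across tables: %s",
                 allOtus[duplicated(allOtus)][1L]), call. = FALSE)
  rel <- lapply(tables, function(tb) abundances(relativeAbundance(tb))[, ref,
                                                                       drop = FALSE])
  otuTable(do.call(rbind, rel), relative = TRUE)
}
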