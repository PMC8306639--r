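#' Read an OTU table from disk
#'
#' The canonical format is tab-separated text with OTUs as rows: the first
#' column holds OTU ids (header `otu_id` or anything else), the remaining
#' header fields are sample ids, and cells are numeric. BIOM 1.0 JSON is
#' supported as an optional reader via the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom-json"`.
#' @param relative logical; set `TRUE` if the file stores relative
#'   abundances.
#' @return An [OtuTable-class]; row and sample order are preserved from the
#'   file.
#' @seealso [writeOtuTable()]
#' @export
readOtuTable <- function(path, format = c("tsv", "biom-json"),
                         relative = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otuTable(m, relative = relative))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 1L)
    stop(sprintf("format error in %s: no columns", path), call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("format error in %s: duplicated OTU id '%s'",
                 path, ids[duplicated(ids)][1L]), call. = FALSE)
  vals <- df[, -1L, drop = FALSE]
  if (nrow(vals) == 0L) {
    m <- matrix(numeric(0), 0L, ncol(vals),
                dimnames = list(NULL, names(vals)))
    return(otuTable(m, relative = relative))
  }
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1L]
      stop(sprintf(
        "format error in %s: non-numeric cell in column '%s'%s",
        path, names(vals)[j],
        if (!is.na(bad)) sprintf(", row %d", bad) else ""), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  otuTable(m, relative = relative)
}

#' Write an OTU table to disk
#'
#' Writes tab-separated text re-readable by [readOtuTable()] (first column
#' `otu_id`, one column per sample). Relative abundances are serialized at
#' full double precision (15 significant digits), so a write/read round
#' trip changes values by less than 1e-9. BIOM 1.0 JSON output is available
#' via the biomformat package.
#'
#' @param table an [OtuTable-class].
#' @param path output file path; the parent directory must exist.
#' @param format `"tsv"` (default) or `"biom-json"`.
#' @return Invisibly, `path`.
#' @export
writeOtuTable <- function(table, path, format = c("tsv", "biom-json")) {
  stopifnot(is(table, "OtuTable"))
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::make_biom(data = abundances(table))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  m <- abundances(table)
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(m) == 0L)
    df <- data.frame(matrix(nrow = 0, ncol = ncol(m) + 1L,
                            dimnames = list(NULL, c("otu_id", colnames(m)))),
                     check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-separated text whose first column is the OTU id followed by up to six
#' rank columns (domain, phylum, class, order, family, genus). Missing ranks
#' may be empty.
#'
#' @param path file path.
#' @return data.frame with OTU ids as row names and one column per rank.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated OTU id in taxonomy: %s",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  if (ncol(df) - 1L > 6L)
    stop("taxonomy lineage must have at most 6 rank columns", call. = FALSE)
  out <- df[, -1L, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Read a sample metadata table
#'
#' Tab-separated text whose first column is the sample id followed by factor
#' columns (e.g. soil, plant, treatment). All factor columns must be filled
#' for every sample.
#'
#' @param path file path.
#' @return data.frame with sample ids as row names; character columns are
#'   converted to factors.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated sample id in metadata: %s",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  out <- df[, -1L, drop = FALSE]
  rownames(out) <- ids
  for (j in seq_along(out)) {
    if (anyNA(out[[j]]) || any(out[[j]] == ""))
      stop(sprintf("metadata factor '%s' has missing values for some samples",
                   names(out)[j]), call. = FALSE)
    if (is.character(out[[j]])) out[[j]] <- factor(out[[j]])
  }
  out
}
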