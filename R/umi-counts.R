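#' UMI count matrix container
#'
#' A light container for a gene-by-cell matrix of UMI counts, carrying gene
#' identifiers, cell barcodes and (optionally) a per-cell cell-type label.
#' Counts are stored sparsely; library sizes are always the column sums.
#'
#' @param counts A gene-by-cell matrix of nonnegative integer counts (base
#'   matrix or any [Matrix::Matrix()] class). Row names are taken as gene
#'   identifiers and column names as barcodes when `gene_ids`/`barcodes` are
#'   not supplied.
#' @param gene_ids Character vector of unique gene identifiers (one per row).
#' @param barcodes Character vector of unique cell barcodes (one per column).
#' @param labels Optional character vector of cell-type labels, either
#'   unnamed (in column order) or named by barcode.
#'
#' @return An object of class `umi_counts`: a list with elements `counts`
#'   (a `dgCMatrix` with dimnames), and `labels` (named character or `NULL`).
#' @export
#' @examples
#' m <- umi_counts(matrix(0:3, 2, 2), gene_ids = c("g1", "g2"),
#'                 barcodes = c("c1", "c2"))
#' library_sizes(m)
umi_counts <- function(counts, gene_ids = NULL, barcodes = NULL, labels = NULL) {
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(barcodes)) barcodes <- colnames(counts)
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene%0*d", nchar(nrow(counts)), seq_len(nrow(counts)))
  if (is.null(barcodes))
    barcodes <- sprintf("cell%0*d", nchar(ncol(counts)), seq_len(ncol(counts)))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (length(gene_ids) != nrow(counts))
    stop("'gene_ids' must have one entry per row")
  if (length(barcodes) != ncol(counts))
    stop("'barcodes' must have one entry per column")
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    stop("counts must be nonnegative integers")
  dimnames(counts) <- list(as.character(gene_ids), as.character(barcodes))
  if (!is.null(labels)) {
    if (is.null(names(labels))) {
      if (length(labels) != ncol(counts))
        stop("unnamed 'labels' must have one entry per cell")
      names(labels) <- colnames(counts)
    } else {
      missing <- setdiff(colnames(counts), names(labels))
      if (length(missing))
        stop("labels missing for barcodes: ", paste(utils::head(missing, 5), collapse = ", "))
      labels <- labels[colnames(counts)]
    }
    labels <- as.character(stats::setNames(labels, names(labels)))
    names(labels) <- colnames(counts)
  }
  structure(list(counts = counts, labels = labels), class = "umi_counts")
}

#' @export
print.umi_counts <- function(x, ...) {
  cat(sprintf("umi_counts: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total UMIs: %s; median library size: %s\n",
              format(sum(x$counts), big.mark = ","),
              format(stats::median(library_sizes(x)))))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.umi_counts <- function(x) dim(x$counts)

#' Per-cell library sizes
#'
#' Library size of cell `c` is the column sum `s_c` of the count matrix —
#' the offset used by all count models in this package.
#'
#' @param m A [umi_counts()] object.
#' @return Named numeric vector of per-cell total UMIs.
#' @export
library_sizes <- function(m) {
  stopifnot(inherits(m, "umi_counts"))
  Matrix::colSums(m$counts)
}

#' Subset a umi_counts object by gene/cell index
#'
#' @param m A [umi_counts()] object.
#' @param genes,cells Index vectors (logical, integer or character) into rows
#'   and columns; `NULL` keeps everything.
#' @return A [umi_counts()] object.
#' @export
subset_counts <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "umi_counts"))
  cnt <- m$counts
  if (!is.null(genes)) cnt <- cnt[genes, , drop = FALSE]
  if (!is.null(cells)) cnt <- cnt[, cells, drop = FALSE]
  lab <- if (is.null(m$labels)) NULL else m$labels[colnames(cnt)]
  umi_counts(cnt, labels = lab)
}

#' Read and write 10x-style MatrixMarket count triplets
#'
#' `read_10x_counts()` reads `matrix.mtx`, `features.tsv` and `barcodes.tsv`
#' from a directory (the uncompressed 10x triplet dialect); `write_10x_counts()`
#' writes them, plus `labels.tsv` (barcode, label) when labels are present.
#'
#' @param dir Directory containing (or to receive) the triplet.
#' @param m A [umi_counts()] object (writer only).
#' @return `read_10x_counts()` returns a [umi_counts()]; `write_10x_counts()`
#'   returns `dir` invisibly.
#' @export
read_10x_counts <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  bc <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feat, bc))
    if (!file.exists(f)) stop("missing file: ", f)
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  labels <- NULL
  labf <- file.path(dir, "labels.tsv")
  if (file.exists(labf)) {
    lab <- utils::read.table(labf, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    labels <- stats::setNames(lab[[2]], lab[[1]])
  }
  umi_counts(counts, gene_ids = features[[1]], barcodes = barcodes,
             labels = labels)
}

#' @rdname read_10x_counts
#' @export
write_10x_counts <- function(m, dir) {
  stopifnot(inherits(m, "umi_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = rownames(m$counts), name = rownames(m$counts)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(m$labels))
    utils::write.table(data.frame(barcode = names(m$labels), label = m$labels),
                       file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
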