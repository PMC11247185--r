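#' Quality control and pseudonegative-control construction
#'
#' `filter_cells()` removes nuclei with low library sizes or few expressed
#' genes (both conditions must hold for a cell to be kept);
#' `drop_zero_genes()` discards genes with zero counts across all retained
#' cells; `subset_by_celltype()` restricts a labeled matrix to one cell type,
#' the pseudonegative-control construction: within a single (roughly
#' homogeneous) cell type, residual variation bounds the technical
#' overdispersion from above.
#'
#' The pipeline applies these in the order cells, then genes — the order
#' matters, since removing cells can zero out genes.
#'
#' @param m A [umi_counts()] object.
#' @param min_library_size Minimum total UMIs per cell.
#' @param min_expressed_genes Minimum number of genes with count > 0 per cell.
#' @param celltype Cell-type label to keep (must occur in `m$labels`).
#' @return A [umi_counts()] object.
#' @export
#' @examples
#' sim <- simulate_counts(20, 50, model = "poisson", seed = 1)
#' dim(filter_cells(sim$counts, min_library_size = 100))
filter_cells <- function(m, min_library_size = 100, min_expressed_genes = 100) {
  stopifnot(inherits(m, "umi_counts"),
            min_library_size >= 0, min_expressed_genes >= 0)
  s <- library_sizes(m)
  n_expr <- Matrix::colSums(m$counts > 0)
  keep <- s >= min_library_size & n_expr >= min_expressed_genes
  if (!any(keep))
    stop("no cells pass QC (min_library_size = ", min_library_size,
         ", min_expressed_genes = ", min_expressed_genes, ")")
  subset_counts(m, cells = which(keep))
}

#' @rdname filter_cells
#' @export
drop_zero_genes <- function(m) {
  stopifnot(inherits(m, "umi_counts"))
  keep <- Matrix::rowSums(m$counts) > 0
  subset_counts(m, genes = which(keep))
}

#' @rdname filter_cells
#' @export
subset_by_celltype <- function(m, celltype) {
  stopifnot(inherits(m, "umi_counts"))
  if (is.null(m$labels)) stop("matrix carries no cell-type labels")
  if (!celltype %in% m$labels)
    stop("unknown cell type '", celltype, "'; available: ",
         paste(sort(unique(m$labels)), collapse = ", "))
  drop_zero_genes(subset_counts(m, cells = which(m$labels == celltype)))
}

#' Run the standard QC sequence
#'
#' Cells first ([filter_cells()]), then genes ([drop_zero_genes()]), then an
#' optional cell-type subset ([subset_by_celltype()]).
#'
#' @inheritParams filter_cells
#' @param celltype Optional label; `NULL` skips the subset step.
#' @return A [umi_counts()] object.
#' @export
qc_pipeline <- function(m, min_library_size = 100, min_expressed_genes = 100,
                        celltype = NULL) {
  m <- filter_cells(m, min_library_size, min_expressed_genes)
  m <- drop_zero_genes(m)
  if (!is.null(celltype)) m <- subset_by_celltype(m, celltype)
  m
}
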