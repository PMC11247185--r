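#' Per-cell marker UMI ratio
#'
#' For each cell, the ratio of summed UMI counts over one marker set to
#' summed counts over another, with a pseudocount added to both sums to
#' avoid division by zero. Used to contrast, e.g., astrocyte against qNSC
#' marker expression within one population of nuclei.
#'
#' @param m A [umi_counts()] object.
#' @param markers_num,markers_den Character vectors of gene ids; markers not
#'   present in the matrix are dropped with a warning, but each list must
#'   resolve to at least one gene.
#' @param pseudocount Added to numerator and denominator sums (default 1).
#' @return Named numeric vector of per-cell ratios.
#' @export
marker_ratio <- function(m, markers_num, markers_den, pseudocount = 1) {
  stopifnot(inherits(m, "umi_counts"))
  resolve <- function(ids, what) {
    hit <- intersect(ids, rownames(m$counts))
    if (length(hit) < length(ids))
      warning(length(ids) - length(hit), " ", what,
              " marker(s) not in the matrix; dropped")
    if (!length(hit)) stop("no ", what, " markers found in the matrix")
    hit
  }
  num <- resolve(markers_num, "numerator")
  den <- resolve(markers_den, "denominator")
  top <- Matrix::colSums(m$counts[num, , drop = FALSE]) + pseudocount
  bot <- Matrix::colSums(m$counts[den, , drop = FALSE]) + pseudocount
  top / bot
}

#' Spearman-correlation reference annotation
#'
#' A minimal reference-based cell-type annotator: each cell is correlated
#' (Spearman, average ranks for ties) with each reference profile over the
#' union of the marker genes, and assigned the best-correlated type. Labels
#' are pruned by a margin rule — when the best correlation exceeds the
#' second best by less than `prune_delta`, the cell is left `"unassigned"`
#' (ambiguous profile). Cells with constant expression over the marker
#' union are unassigned with a warning. Being rank-based, assignments are
#' invariant to any monotone transformation of a cell's counts.
#'
#' @param m A [umi_counts()] object.
#' @param reference_profiles Gene-by-type numeric matrix of reference mean
#'   expression (rownames are gene ids, colnames type labels; >= 2 types).
#' @param markers Named list mapping cell type to marker gene ids, or a
#'   data.frame with columns `celltype`, `gene_id`. Markers missing from
#'   both matrix and reference are dropped with a warning.
#' @param prune_delta Minimum winning margin in correlation units
#'   (default 0.05); 0 disables pruning except for exact ties.
#' @return Named character vector of labels (or `"unassigned"`), one per
#'   cell.
#' @export
spearman_annotate <- function(m, reference_profiles, markers,
                              prune_delta = 0.05) {
  stopifnot(inherits(m, "umi_counts"), ncol(reference_profiles) >= 2)
  if (is.data.frame(markers))
    markers <- split(markers$gene_id, markers$celltype)
  marker_union <- unique(unlist(markers))
  usable <- Reduce(intersect, list(marker_union, rownames(m$counts),
                                   rownames(reference_profiles)))
  if (length(usable) < length(marker_union))
    warning(length(marker_union) - length(usable),
            " marker(s) absent from matrix or reference; dropped")
  if (length(usable) < 2) stop("fewer than 2 usable marker genes")
  expr <- as.matrix(m$counts[usable, , drop = FALSE])
  ref <- reference_profiles[usable, , drop = FALSE]
  types <- colnames(ref)

  labels <- vapply(seq_len(ncol(expr)), function(c) {
    v <- expr[, c]
    if (stats::sd(v) == 0) {
      warning("cell ", colnames(expr)[c],
              ": constant expression over markers; unassigned")
      return("unassigned")
    }
    rho <- suppressWarnings(
      apply(ref, 2, function(p) stats::cor(v, p, method = "spearman")))
    rho[is.na(rho)] <- -Inf
    ord <- order(rho, decreasing = TRUE)
    if (rho[ord[1]] - rho[ord[2]] < prune_delta ||
        !is.finite(rho[ord[1]])) "unassigned" else types[ord[1]]
  }, character(1))
  stats::setNames(labels, colnames(expr))
}

#' Cross-tabulate reference and assigned cell-type labels
#'
#' Builds the full concordance table of reference labels (rows) against
#' assigned labels (columns), always including an explicit `"unassigned"`
#' column. A merge map can collapse labels first (e.g., excitatory and
#' inhibitory neurons into a combined "Neurons" class) on either side.
#'
#' @param labels_ref,labels_assigned Named character vectors over the same
#'   barcodes (order-insensitive; an error is raised on a barcode mismatch).
#' @param merge_map Optional named character vector `c(old = new, ...)`
#'   applied to both label sets before tabulation.
#' @return A contingency matrix (reference x assigned) whose entries sum to
#'   the number of cells.
#' @export
concordance <- function(labels_ref, labels_assigned, merge_map = NULL) {
  if (is.null(names(labels_ref)) || is.null(names(labels_assigned)))
    stop("label vectors must be named by barcode")
  if (!setequal(names(labels_ref), names(labels_assigned)))
    stop("barcode mismatch between label sets")
  labels_assigned <- labels_assigned[names(labels_ref)]
  apply_map <- function(l) {
    if (is.null(merge_map)) return(l)
    hit <- l %in% names(merge_map)
    l[hit] <- merge_map[l[hit]]
    l
  }
  ref <- apply_map(as.character(labels_ref))
  asg <- apply_map(as.character(labels_assigned))
  cols <- unique(c(sort(unique(asg[asg != "unassigned"])), "unassigned"))
  tab <- table(reference = ref,
               assigned = factor(asg, levels = cols))
  unclass(tab)
}

#' Annotation accuracy against known labels
#'
#' Share of cells whose assigned label equals the reference label;
#' unassigned cells count as incorrect unless `drop_unassigned = TRUE`.
#'
#' @param labels_ref,labels_assigned Named label vectors over the same
#'   cells.
#' @param drop_unassigned Exclude unassigned cells from the denominator.
#' @return A single number in \[0, 1\].
#' @export
annotation_accuracy <- function(labels_ref, labels_assigned,
                                drop_unassigned = FALSE) {
  labels_assigned <- labels_assigned[names(labels_ref)]
  if (drop_unassigned) {
    keep <- labels_assigned != "unassigned"
    labels_ref <- labels_ref[keep]
    labels_assigned <- labels_assigned[keep]
  }
  if (!length(labels_ref)) return(NA_real_)
  mean(labels_assigned == labels_ref)
}
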