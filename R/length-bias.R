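#' Per-gene lengths on the two definitions
#'
#' For each transcript, the unspliced ("preandmrna") length is its genomic
#' span (exons plus introns) and the spliced ("transcript") length is the
#' sum of its exon lengths. Genes are summarized by the maximum over their
#' transcripts for both definitions, so the preandmrna length is always at
#' least the transcript length.
#'
#' @param models A [gene_model_set()].
#' @return A data.frame with `gene_id`, `preandmrna_length`,
#'   `transcript_length`.
#' @export
gene_lengths <- function(models) {
  stopifnot(inherits(models, "gene_model_set"))
  rows <- lapply(names(models$genes), function(gid) {
    txs <- models$genes[[gid]]$transcripts
    span <- vapply(txs, function(ex) max(ex[, 2]) - min(ex[, 1]), numeric(1))
    exonic <- vapply(txs, function(ex) sum(ex[, 2] - ex[, 1]), numeric(1))
    data.frame(gene_id = gid, preandmrna_length = as.integer(max(span)),
               transcript_length = as.integer(max(exonic)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total counts per gene
#'
#' Sum of counts across all cells (row sums) — the per-gene expression
#' totals whose relationship with gene length is the length bias.
#'
#' @param m A [umi_counts()] object.
#' @return Named numeric vector of per-gene totals.
#' @export
total_gene_counts <- function(m) {
  stopifnot(inherits(m, "umi_counts"))
  Matrix::rowSums(m$counts)
}

#' Equal-count length bins
#'
#' Sorts genes ascending by length and cuts them into `n_bins` consecutive
#' blocks whose sizes differ by at most one (bin 1 holds the shortest
#' genes). Ties in length are broken by gene identifier, so the binning is
#' deterministic.
#'
#' @param lengths Named numeric vector of gene lengths (names are gene ids;
#'   unnamed vectors are given positional ids).
#' @param n_bins Number of bins (at most the number of genes).
#' @return Named integer vector of bin ids in 1..n_bins, in the input order.
#' @export
bin_by_length <- function(lengths, n_bins = 10) {
  if (n_bins < 1) stop("'n_bins' must be >= 1")
  G <- length(lengths)
  if (n_bins > G) stop("'n_bins' exceeds the number of genes")
  ids <- names(lengths)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(G))
  ord <- order(lengths, ids, method = "radix")
  sizes <- diff(floor(G * (0:n_bins) / n_bins))
  bin_sorted <- rep.int(seq_len(n_bins), sizes)
  bins <- integer(G)
  bins[ord] <- bin_sorted
  stats::setNames(bins, ids)
}

#' Per-bin quantiles of gene totals
#'
#' Median, 25th, and 75th percentile of the per-gene totals within each
#' length bin, using linear interpolation between order statistics
#' (quantile type 7).
#'
#' @param totals Numeric vector of per-gene totals.
#' @param bin_ids Integer bin assignment, as from [bin_by_length()].
#' @return A data.frame with `bin_id`, `n`, `q25`, `median`, `q75`.
#' @export
bin_summary <- function(totals, bin_ids) {
  stopifnot(length(totals) == length(bin_ids))
  if (anyNA(bin_ids) || any(table(bin_ids) == 0)) stop("empty bin")
  out <- do.call(rbind, lapply(sort(unique(bin_ids)), function(b) {
    v <- totals[bin_ids == b]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(bin_id = b, n = length(v), q25 = q[1], median = q[2],
               q75 = q[3])
  }))
  rownames(out) <- NULL
  out
}

#' Count internal poly-A n-mers in a sequence
#'
#' Counts maximal runs of consecutive `A` of length at least `n` (run-based
#' convention: a run of 8 A's contains one poly-A 8-mer, not five
#' overlapping windows). The downstream use is the dichotomy "has at least
#' one internal poly-A n-mer" vs none, for which the two conventions agree.
#'
#' @param sequence A nucleotide string over A/C/G/T/N (case-insensitive).
#' @param n Minimum run length (>= 1).
#' @return Integer count of maximal A-runs of length >= n.
#' @export
#' @examples
#' polyA_nmer_count("AAACAAAA", 4)  # 1
polyA_nmer_count <- function(sequence, n) {
  stopifnot(n >= 1, length(sequence) == 1)
  runs <- gregexpr("A+", toupper(sequence))[[1]]
  if (runs[1] == -1) return(0L)
  sum(attr(runs, "match.length") >= n)
}

#' Per-gene maximum internal poly-A count
#'
#' Counts poly-A n-mers in every spliced and unspliced transcript sequence
#' of each gene (in transcript orientation) and summarizes at gene level by
#' the maximum over all of them. A gene "has" an internal poly-A n-mer when
#' this maximum is at least one.
#'
#' @param models A [gene_model_set()].
#' @param genome Named character vector of chromosome sequences.
#' @param n Minimum run length; typical choices are 6, 8, 10, 12.
#' @return A data.frame with `gene_id`, `polyA_max`, `has_polyA`.
#' @export
gene_polyA_max <- function(models, genome, n = 8) {
  spliced <- spliced_transcript_sequences(models, genome)
  unspliced <- unspliced_transcript_sequences(models, genome)
  all_seq <- rbind(as.data.frame(spliced)[, c("gene_id", "sequence")],
                   as.data.frame(unspliced)[, c("gene_id", "sequence")])
  counts <- vapply(all_seq$sequence, polyA_nmer_count, integer(1), n = n,
                   USE.NAMES = FALSE)
  mx <- tapply(counts, all_seq$gene_id, max)
  gid <- names(models$genes)
  data.frame(gene_id = gid, polyA_max = as.integer(mx[gid]),
             has_polyA = as.vector(mx[gid] >= 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-scale Pearson correlation of totals with gene length
#'
#' Pearson correlation of log10(total) against log10(length) over genes
#' with positive totals (zero-total genes are excluded; their number is
#' returned). No pseudocount is added.
#'
#' @param totals Per-gene total counts.
#' @param lengths Per-gene lengths (same order).
#' @return A list: `r` (Pearson correlation), `n_used`, `n_zero_excluded`.
#' @export
log_length_correlation <- function(totals, lengths) {
  stopifnot(length(totals) == length(lengths), all(lengths > 0))
  use <- totals > 0
  if (sum(use) < 3) stop("fewer than 3 genes with positive totals")
  list(r = stats::cor(log10(totals[use]), log10(lengths[use])),
       n_used = sum(use), n_zero_excluded = sum(!use))
}

#' Local-regression trend of totals against length
#'
#' Loess (local linear regression with tricube weights) of log10(total)
#' on log10(length), evaluated on a regular grid across the observed
#' length range. Genes with zero totals are excluded.
#'
#' @param lengths,totals Per-gene lengths and totals.
#' @param span Loess span in (0, 1].
#' @param n_grid Number of evaluation points.
#' @return A data.frame with `log10_length` and `log10_total` (the fitted
#'   curve).
#' @export
trend_curve <- function(lengths, totals, span = 0.75, n_grid = 100) {
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  use <- totals > 0
  if (sum(use) < 10) stop("need at least 10 genes with positive totals")
  x <- log10(lengths[use]); y <- log10(totals[use])
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = n_grid)
  data.frame(log10_length = grid,
             log10_total = stats::predict(fit, data.frame(x = grid)))
}

#' Full length-bias analysis for one count matrix
#'
#' Combines gene lengths, totals, equal-count binning with per-bin
#' quantiles, internal poly-A detection, and the log-scale correlations for
#' both length definitions.
#'
#' @param m A [umi_counts()] object whose gene ids match `models`.
#' @param models A [gene_model_set()].
#' @param genome Named character vector of chromosome sequences.
#' @param n_bins Number of length bins.
#' @param polyA_n Poly-A run-length cutoff.
#' @return An object of class `length_bias`: `per_gene` (lengths, totals,
#'   bin, poly-A columns), `per_bin` ([bin_summary()] on preandmrna bins),
#'   `correlations` (list `preandmrna`, `transcript` of
#'   [log_length_correlation()] results).
#' @export
length_bias_analysis <- function(m, models, genome, n_bins = 10, polyA_n = 8) {
  stopifnot(inherits(m, "umi_counts"))
  lens <- gene_lengths(models)
  common <- intersect(rownames(m$counts), lens$gene_id)
  if (length(common) < n_bins)
    stop("fewer genes shared between counts and models than bins")
  lens <- lens[match(common, lens$gene_id), ]
  totals <- total_gene_counts(m)[common]
  bins <- bin_by_length(stats::setNames(lens$preandmrna_length, common),
                        n_bins)
  pa <- gene_polyA_max(models, genome, n = polyA_n)
  pa <- pa[match(common, pa$gene_id), ]
  per_gene <- data.frame(gene_id = common,
                         preandmrna_length = lens$preandmrna_length,
                         transcript_length = lens$transcript_length,
                         total_count = as.numeric(totals),
                         bin_id = as.integer(bins[common]),
                         polyA_max = pa$polyA_max, has_polyA = pa$has_polyA,
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    per_gene = per_gene,
    per_bin = bin_summary(per_gene$total_count, per_gene$bin_id),
    correlations = list(
      preandmrna = log_length_correlation(per_gene$total_count,
                                          per_gene$preandmrna_length),
      transcript = log_length_correlation(per_gene$total_count,
                                          per_gene$transcript_length))),
    class = "length_bias")
}

#' Length-bias diagnostic panels
#'
#' Two panels: per-bin total-count quantiles against length bin (median
#' points, quartile dashes), and the per-gene log10 total against log10
#' preandmrna length colored by internal poly-A status, with a loess trend
#' per group.
#'
#' @param x A [length_bias_analysis()] result.
#' @param which Subset of `1:2`.
#' @param span Loess span for the trend curves.
#' @param ... Passed to the plot calls.
#' @return `x`, invisibly.
#' @export
plot.length_bias <- function(x, which = 1:2, span = 0.75, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  pg <- x$per_gene
  if (1 %in% which) {
    pb <- x$per_bin
    graphics::plot(pb$bin_id, log10(pb$median + 1), pch = 16, type = "b",
                   ylim = range(log10(c(pb$q25, pb$q75) + 1)),
                   xlab = "preandmrna length bin",
                   ylab = "log10(total count + 1)",
                   main = "Length bins", ...)
    graphics::lines(pb$bin_id, log10(pb$q25 + 1), lty = 2)
    graphics::lines(pb$bin_id, log10(pb$q75 + 1), lty = 2)
  }
  if (2 %in% which) {
    use <- pg$total_count > 0
    cols <- ifelse(pg$has_polyA, "red", "blue")
    graphics::plot(log10(pg$preandmrna_length[use]),
                   log10(pg$total_count[use]), col = cols[use], pch = 16,
                   cex = 0.4, xlab = "log10 preandmrna length",
                   ylab = "log10 total count",
                   main = "Internal poly-A", ...)
    for (grp in c(TRUE, FALSE)) {
      sel <- use & pg$has_polyA == grp
      if (sum(sel) >= 10) {
        tc <- trend_curve(pg$preandmrna_length[sel], pg$total_count[sel],
                          span = span)
        graphics::lines(tc$log10_length, tc$log10_total,
                        col = if (grp) "red" else "blue", lwd = 2)
      }
    }
    graphics::legend("topleft", c("has poly-A", "no poly-A"), bty = "n",
                     col = c("red", "blue"), pch = 16)
  }
  invisible(x)
}

#' @export
print.length_bias <- function(x, ...) {
  cat(sprintf("length_bias: %d genes, %d bins; %d genes with internal poly-A\n",
              nrow(x$per_gene), nrow(x$per_bin), sum(x$per_gene$has_polyA)))
  cat(sprintf("log10 Pearson r: %.3f (preandmrna length), %.3f (transcript length)\n",
              x$correlations$preandmrna$r, x$correlations$transcript$r))
  invisible(x)
}
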