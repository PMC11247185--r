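#' Gene model set
#'
#' Per-gene transcript structures used for reference construction and length
#' computations. Each gene carries a chromosome, a strand, and one or more
#' transcripts; each transcript is an ordered set of exon intervals. All
#' intervals are held 0-based half-open internally; GTF input/output converts
#' to/from the 1-based closed convention of that format.
#'
#' @param genes Named list (by gene id). Each element is a list with fields
#'   `chromosome` (string), `strand` (`"+"` or `"-"`), and `transcripts`: a
#'   named list (by transcript id) of two-column integer matrices with columns
#'   `start`, `end` (0-based half-open), rows sorted by start.
#' @return An object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes) {
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stop("'genes' must be a uniquely named list")
  for (gid in names(genes)) {
    g <- genes[[gid]]
    if (!all(c("chromosome", "strand", "transcripts") %in% names(g)))
      stop("gene ", gid, ": needs chromosome, strand, transcripts")
    if (!g$strand %in% c("+", "-"))
      stop("gene ", gid, ": strand must be '+' or '-'")
    if (length(g$transcripts) == 0 || is.null(names(g$transcripts)))
      stop("gene ", gid, ": needs >= 1 named transcript")
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      if (!is.matrix(ex) || ncol(ex) != 2 || nrow(ex) == 0)
        stop("transcript ", tid, ": exons must be a nonempty 2-column matrix")
      if (any(ex[, 2] <= ex[, 1]))
        stop("transcript ", tid, ": empty or inverted exon interval")
      if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
        stop("transcript ", tid, ": exons must be sorted and disjoint")
      colnames(genes[[gid]]$transcripts[[tid]]) <- c("start", "end")
    }
  }
  structure(list(genes = genes), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  ntx <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat(sprintf("gene_model_set: %d genes, %d transcripts on %d sequence(s)\n",
              length(x$genes), ntx,
              length(unique(vapply(x$genes, `[[`, "", "chromosome")))))
  invisible(x)
}

#' @export
length.gene_model_set <- function(x) length(x$genes)

#' Flat exon table of a gene model set
#'
#' @param models A [gene_model_set()].
#' @return A data.frame with one row per exon: `gene_id`, `transcript_id`,
#'   `chromosome`, `strand`, `start`, `end` (0-based half-open).
#' @export
exon_table <- function(models) {
  stopifnot(inherits(models, "gene_model_set"))
  rows <- list()
  for (gid in names(models$genes)) {
    g <- models$genes[[gid]]
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid, chromosome = g$chromosome,
        strand = g$strand, start = ex[, 1], end = ex[, 2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read gene models from a GTF file
#'
#' Parses exon features of a GTF annotation (1-based closed coordinates)
#' into a [gene_model_set()] (0-based half-open internally). Uses
#' `rtracklayer` when available, otherwise a minimal reader for the
#' tab-separated GTF layout.
#'
#' @param path Path to a GTF file.
#' @return A [gene_model_set()].
#' @export
read_gtf_models <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    df <- data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     gene_id = gr$gene_id, transcript_id = gr$transcript_id,
                     stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                             comment.char = "#", stringsAsFactors = FALSE)
    raw <- raw[raw[[3]] == "exon", ]
    attr_get <- function(a, key) {
      m <- regmatches(a, regexpr(paste0(key, ' "[^"]+"'), a))
      sub(paste0(key, ' "([^"]+)"'), "\\1", m)
    }
    df <- data.frame(chromosome = raw[[1]], start = raw[[4]] - 1L,
                     end = raw[[5]], strand = raw[[7]],
                     gene_id = attr_get(raw[[9]], "gene_id"),
                     transcript_id = attr_get(raw[[9]], "transcript_id"),
                     stringsAsFactors = FALSE)
  }
  genes <- list()
  for (gid in unique(df$gene_id)) {
    sub <- df[df$gene_id == gid, ]
    txs <- list()
    for (tid in unique(sub$transcript_id)) {
      ex <- sub[sub$transcript_id == tid, c("start", "end")]
      ex <- as.matrix(ex[order(ex$start), ])
      dimnames(ex) <- list(NULL, c("start", "end"))
      txs[[tid]] <- ex
    }
    genes[[gid]] <- list(chromosome = sub$chromosome[1], strand = sub$strand[1],
                         transcripts = txs)
  }
  gene_model_set(genes)
}

#' Write gene models to a GTF file
#'
#' Emits gene, transcript and exon features in 1-based closed GTF
#' coordinates.
#'
#' @param models A [gene_model_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf_models <- function(models, path) {
  stopifnot(inherits(models, "gene_model_set"))
  lines <- character(0)
  fmt <- function(chrom, feat, start0, end0, strand, attrs)
    sprintf("%s\tnucdist\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start0 + 1L, end0, strand, attrs)
  for (gid in names(models$genes)) {
    g <- models$genes[[gid]]
    span <- gene_span(g)
    ga <- sprintf('gene_id "%s";', gid)
    lines <- c(lines, fmt(g$chromosome, "gene", span[1], span[2], g$strand, ga))
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      ta <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      lines <- c(lines,
                 fmt(g$chromosome, "transcript", min(ex[, 1]), max(ex[, 2]),
                     g$strand, ta),
                 fmt(g$chromosome, "exon", ex[, 1], ex[, 2], g$strand, ta))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# [min start, max end) over all transcripts of one gene entry
gene_span <- function(g) {
  starts <- vapply(g$transcripts, function(ex) min(ex[, 1]), numeric(1))
  ends <- vapply(g$transcripts, function(ex) max(ex[, 2]), numeric(1))
  c(min(starts), max(ends))
}

#' Read and write genome sequences as FASTA
#'
#' Thin wrappers around `Biostrings` keeping the genome as a named character
#' vector (one element per chromosome).
#'
#' @param path FASTA file path.
#' @param genome Named character vector of sequences (writer only).
#' @return `read_genome_fasta()` returns a named character vector.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
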