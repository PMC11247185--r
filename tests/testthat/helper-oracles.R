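# Independent brute-force oracles used to cross-check interval arithmetic,
# sequence extraction and poly-A counting. These deliberately avoid the
# package's own code paths.

# reverse complement by explicit character operations
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# per-base classifier: maximal intervals within the gene span that are not
# exonic in any isoform (0-based half-open in/out)
oracle_collapse_introns <- function(transcripts) {
  ex <- do.call(rbind, transcripts)
  span <- c(min(ex[, 1]), max(ex[, 2]))
  n <- span[2] - span[1]
  exonic <- logical(n)
  for (i in seq_len(nrow(ex)))
    exonic[(ex[i, 1] - span[1] + 1):(ex[i, 2] - span[1])] <- TRUE
  out <- NULL
  i <- 1
  while (i <= n) {
    if (!exonic[i]) {
      j <- i
      while (j < n && !exonic[j + 1]) j <- j + 1
      out <- rbind(out, c(span[1] + i - 1, span[1] + j))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# per-transcript gap enumeration
oracle_separate_introns <- function(ex) {
  if (nrow(ex) < 2) return(matrix(integer(0), 0, 2))
  out <- NULL
  for (i in 1:(nrow(ex) - 1)) out <- rbind(out, c(ex[i, 2], ex[i + 1, 1]))
  out
}

oracle_flank_clip <- function(iv, flank, chrom_len) {
  if (nrow(iv) == 0) return(iv)
  t(apply(iv, 1, function(r)
    c(max(0, r[1] - flank), min(chrom_len, r[2] + flank))))
}

# character-by-character run scanner for poly-A runs of length >= n
oracle_polyA_runs <- function(s, n) {
  chars <- strsplit(toupper(s), "")[[1]]
  count <- 0L; run <- 0L
  for (ch in c(chars, "X")) {
    if (ch == "A") run <- run + 1L
    else {
      if (run >= n) count <- count + 1L
      run <- 0L
    }
  }
  count
}

# overlapping sliding-window count (the alternative convention)
oracle_polyA_windows <- function(s, n) {
  chars <- strsplit(toupper(s), "")[[1]]
  if (length(chars) < n) return(0L)
  sum(vapply(seq_len(length(chars) - n + 1),
             function(i) all(chars[i:(i + n - 1)] == "A"), logical(1)))
}

# type-7 quantile by explicit order statistics
oracle_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# tiny hand-built gene model set helpers
toy_models <- function(transcripts, chrom = "chr1", strand = "+",
                       gene_id = "g1") {
  gene_model_set(stats::setNames(list(list(
    chromosome = chrom, strand = strand, transcripts = transcripts)),
    gene_id))
}

toy_counts <- function(mat, labels = NULL) {
  umi_counts(mat,
             gene_ids = sprintf("g%d", seq_len(nrow(mat))),
             barcodes = sprintf("c%d", seq_len(ncol(mat))),
             labels = labels)
}
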