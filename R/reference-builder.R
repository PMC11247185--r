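#' Target sequence sets for intron-aware reference transcriptomes
#'
#' A `target_sequence_set` is a data.frame of named nucleotide sequences,
#' one row per target, with columns `target_id`, `category` (one of
#' `"spliced"`, `"unspliced"`, `"intron"`), `gene_id`, `transcript_id`
#' (empty string for gene-level collapsed introns) and `sequence`.
#' Attributes `reference_kind` and `flank_bp` record how it was built.
#'
#' @name target_sequence_set
NULL

new_target_set <- function(df, kind = NA_character_, flank_bp = 0L) {
  rownames(df) <- NULL
  if (nrow(df)) {
    if (anyDuplicated(df$target_id)) stop("target ids must be unique")
    if (any(nchar(df$sequence) == 0)) stop("empty target sequence")
  }
  structure(df, class = c("target_sequence_set", "data.frame"),
            reference_kind = kind, flank_bp = flank_bp)
}

#' @export
print.target_sequence_set <- function(x, ...) {
  kind <- attr(x, "reference_kind")
  cat(sprintf("target_sequence_set: %d targets%s\n", nrow(x),
              if (is.na(kind)) "" else sprintf(" (reference '%s', flank %d bp)",
                                               kind, attr(x, "flank_bp"))))
  if (nrow(x)) print(table(category = x$category))
  invisible(x)
}

# sequence of [start, end) on chrom, reverse-complemented for "-" strand
extract_seq <- function(genome, chrom, start, end, strand, what = "interval") {
  if (!chrom %in% names(genome))
    stop("unknown chromosome '", chrom, "' (", what, ")")
  L <- nchar(genome[[chrom]])
  if (start < 0 || end > L)
    stop(what, ": interval [", start, ",", end, ") outside ", chrom,
         " (length ", L, ")")
  s <- toupper(substr(genome[[chrom]], start + 1L, end))
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# stable ordering used for all target sets
order_targets <- function(df) {
  df[order(df$gene_id, df$transcript_id, df$start, method = "radix"), ,
     drop = FALSE]
}

#' Spliced and unspliced transcript target sequences
#'
#' `spliced_transcript_sequences()` concatenates each transcript's exon
#' sequences in genomic order (reverse-complemented for minus-strand genes).
#' `unspliced_transcript_sequences()` takes the full transcript span from
#' first exon start to last exon end, re-adding the intronic regions, so the
#' unspliced sequence is always at least as long as the spliced one.
#'
#' @param models A [gene_model_set()].
#' @param genome Named character vector of chromosome sequences.
#' @return A [target_sequence_set] with one entry per transcript.
#' @export
spliced_transcript_sequences <- function(models, genome) {
  per_transcript_targets(models, genome, spliced = TRUE)
}

#' @rdname spliced_transcript_sequences
#' @export
unspliced_transcript_sequences <- function(models, genome) {
  per_transcript_targets(models, genome, spliced = FALSE)
}

per_transcript_targets <- function(models, genome, spliced) {
  stopifnot(inherits(models, "gene_model_set"))
  rows <- list()
  for (gid in names(models$genes)) {
    g <- models$genes[[gid]]
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      seq <- if (spliced) {
        pieces <- vapply(seq_len(nrow(ex)), function(i)
          extract_seq(genome, g$chromosome, ex[i, 1], ex[i, 2], "+",
                      paste("transcript", tid)), character(1))
        s <- paste(pieces, collapse = "")
        if (g$strand == "-")
          s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
        s
      } else {
        extract_seq(genome, g$chromosome, min(ex[, 1]), max(ex[, 2]),
                    g$strand, paste("transcript", tid))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = if (spliced) tid else paste0(tid, "-U"),
        category = if (spliced) "spliced" else "unspliced",
        gene_id = gid, transcript_id = tid, start = min(ex[, 1]),
        sequence = seq, stringsAsFactors = FALSE)
    }
  }
  df <- order_targets(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  new_target_set(df[, setdiff(names(df), "start")])
}

# intron intervals (before flanking) per transcript: gaps between exons
transcript_gaps <- function(ex) {
  if (nrow(ex) < 2) return(matrix(integer(0), 0, 2))
  cbind(ex[-nrow(ex), 2], ex[-1, 1])
}

# maximal intervals of the gene span not exonic in any isoform
collapse_gaps <- function(g) {
  span <- gene_span(g)
  ex <- do.call(rbind, lapply(g$transcripts, identity))
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  # merge the exon union
  merged <- list()
  cur <- ex[1, ]
  if (nrow(ex) > 1) for (i in 2:nrow(ex)) {
    if (ex[i, 1] <= cur[2]) cur[2] <- max(cur[2], ex[i, 2])
    else { merged[[length(merged) + 1L]] <- cur; cur <- ex[i, ] }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)
  if (nrow(m) < 2) return(matrix(integer(0), 0, 2))
  cbind(m[-nrow(m), 2], m[-1, 1])
}

flank_clip <- function(iv, flank, chrom_len) {
  if (nrow(iv) == 0) return(iv)
  iv[, 1] <- pmax(0L, iv[, 1] - flank)
  iv[, 2] <- pmin(chrom_len, iv[, 2] + flank)
  iv
}

#' Intron target sequences
#'
#' Two definitions of intron targets. In the "separate" approach each gap
#' between consecutive exons of each transcript becomes one target, which may
#' overlap exonic regions of other isoforms of the same gene. In the
#' "collapse" approach the union of all isoforms' exons is subtracted from
#' the gene span and each maximal remaining interval becomes one gene-level
#' target, so collapsed introns are never exonic in any isoform. In both
#' cases every final intron interval is extended by `flank_bp` on each side
#' (to capture reads spanning exon/intron junctions) and clipped to the
#' chromosome; flank-extended targets that come to overlap are kept as
#' distinct targets. Sequences follow the gene strand.
#'
#' @param models A [gene_model_set()].
#' @param genome Named character vector of chromosome sequences.
#' @param flank_bp Nonnegative flank added to each intron interval (default
#'   50, a typical read length).
#' @return A [target_sequence_set] of category `"intron"` targets. Interval
#'   columns `start`, `end` give the flank-extended genomic coordinates.
#' @export
intron_targets_separate <- function(models, genome, flank_bp = 50) {
  intron_targets(models, genome, flank_bp, collapse = FALSE)
}

#' @rdname intron_targets_separate
#' @export
intron_targets_collapse <- function(models, genome, flank_bp = 50) {
  intron_targets(models, genome, flank_bp, collapse = TRUE)
}

intron_targets <- function(models, genome, flank_bp, collapse) {
  stopifnot(inherits(models, "gene_model_set"), flank_bp >= 0)
  rows <- list()
  for (gid in names(models$genes)) {
    g <- models$genes[[gid]]
    if (!g$chromosome %in% names(genome))
      stop("unknown chromosome '", g$chromosome, "'")
    chrom_len <- nchar(genome[[g$chromosome]])
    if (collapse) {
      iv <- flank_clip(collapse_gaps(g), flank_bp, chrom_len)
      if (nrow(iv)) for (i in seq_len(nrow(iv)))
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = sprintf("%s-I%d", gid, i), category = "intron",
          gene_id = gid, transcript_id = "", start = iv[i, 1], end = iv[i, 2],
          stringsAsFactors = FALSE)
    } else {
      for (tid in names(g$transcripts)) {
        iv <- flank_clip(transcript_gaps(g$transcripts[[tid]]), flank_bp,
                         chrom_len)
        if (nrow(iv)) for (i in seq_len(nrow(iv)))
          rows[[length(rows) + 1L]] <- data.frame(
            target_id = sprintf("%s-I%d", tid, i), category = "intron",
            gene_id = gid, transcript_id = tid, start = iv[i, 1],
            end = iv[i, 2], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(new_target_set(data.frame(target_id = character(0),
                                     category = character(0),
                                     gene_id = character(0),
                                     transcript_id = character(0),
                                     start = integer(0), end = integer(0),
                                     sequence = character(0),
                                     stringsAsFactors = FALSE),
                          flank_bp = flank_bp))
  df <- order_targets(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  df$sequence <- vapply(seq_len(nrow(df)), function(i) {
    g <- models$genes[[df$gene_id[i]]]
    extract_seq(genome, g$chromosome, df$start[i], df$end[i], g$strand,
                paste("intron target", df$target_id[i]))
  }, character(1))
  new_target_set(df, flank_bp = flank_bp)
}

#' Build one of the four reference transcriptome target sets
#'
#' Assembles the target sequences for a reference of the given kind:
#' \describe{
#'   \item{transcripts}{spliced transcripts only}
#'   \item{preandmrna}{spliced plus unspliced (pre-mRNA) transcripts}
#'   \item{introncollapse}{spliced transcripts plus gene-level collapsed
#'     intron targets}
#'   \item{intronseparate}{spliced transcripts plus per-transcript intron
#'     targets}
#' }
#' Alongside the sequences, returns the transcript-to-gene map and the list
#' of genome sequence names to use as decoys in a decoy-aware index (the
#' index itself is not built here).
#'
#' @param models A [gene_model_set()].
#' @param genome Named character vector of chromosome sequences.
#' @param kind One of `"transcripts"`, `"preandmrna"`, `"introncollapse"`,
#'   `"intronseparate"`.
#' @param flank_bp Flank for intron targets (ignored by the first two kinds).
#' @return A list with `targets` (a [target_sequence_set]), `t2g`
#'   (data.frame `target_id`, `gene_id`) and `decoys` (character vector of
#'   chromosome names).
#' @export
#' @examples
#' sim <- simulate_annotation(n_genes = 3, seed = 7)
#' ref <- build_reference(sim$models, sim$genome, kind = "preandmrna")
#' table(ref$targets$category)
build_reference <- function(models, genome,
                            kind = c("transcripts", "preandmrna",
                                     "introncollapse", "intronseparate"),
                            flank_bp = 50) {
  kind <- match.arg(kind)
  spliced <- spliced_transcript_sequences(models, genome)
  extra <- switch(kind,
    transcripts = NULL,
    preandmrna = unspliced_transcript_sequences(models, genome),
    introncollapse = intron_targets_collapse(models, genome, flank_bp),
    intronseparate = intron_targets_separate(models, genome, flank_bp))
  keep <- c("target_id", "category", "gene_id", "transcript_id", "sequence")
  df <- as.data.frame(spliced)[, keep]
  if (!is.null(extra)) df <- rbind(df, as.data.frame(extra)[, keep])
  targets <- new_target_set(df, kind = kind,
                            flank_bp = if (kind %in% c("introncollapse",
                                                       "intronseparate"))
                              as.integer(flank_bp) else 0L)
  list(targets = targets,
       t2g = data.frame(target_id = targets$target_id,
                        gene_id = targets$gene_id, stringsAsFactors = FALSE),
       decoys = names(genome))
}

#' Write a reference as the salmon-compatible FASTA / t2g / decoys triple
#'
#' @param ref A list as returned by [build_reference()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `reference.fa`, `t2g.tsv`, `decoys.txt`.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(ref$targets$sequence)
  names(ss) <- ref$targets$target_id
  Biostrings::writeXStringSet(ss, file.path(dir, "reference.fa"))
  utils::write.table(ref$t2g, file.path(dir, "t2g.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(ref$decoys, file.path(dir, "decoys.txt"))
  invisible(dir)
}
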