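#' Simulate a UMI count matrix with known generative parameters
#'
#' Draws a gene-by-cell matrix of UMI counts under one of five count models,
#' sharing the mean structure mu_cg = s_c * pi_g used throughout the package:
#' s_c is a per-cell size factor (lognormal across cells) and pi_g a per-gene
#' relative abundance (gamma draw, normalized to sum to one). The generative
#' parameters are returned alongside the counts so estimators can be checked
#' against simulation truth.
#'
#' Models:
#' \describe{
#'   \item{binomial}{Cell totals are the rounded size factors; each cell's
#'     counts are a multinomial split of its total across genes, so each
#'     gene's count is marginally Binomial(s_c, pi_g) and the column sums
#'     equal the totals exactly.}
#'   \item{poisson}{X_cg ~ Poisson(s_c pi_g).}
#'   \item{nb}{X_cg ~ NB(mean = s_c pi_g, dispersion phi), with
#'     Var = mu + mu^2/phi.}
#'   \item{nb_genewise}{As `nb` with per-gene dispersions phi_g drawn
#'     lognormal around `phi` with log-sd `phi_sdlog`.}
#'   \item{zinb}{NB draws, then each entry independently forced to zero with
#'     probability `zero_inflation_pi` (structural zeros).}
#' }
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param model One of `"binomial"`, `"poisson"`, `"nb"`, `"nb_genewise"`,
#'   `"zinb"`.
#' @param mean_library_size Mean of the per-cell size factor (UMIs/cell).
#' @param libsize_cv Coefficient of variation of the lognormal size factors
#'   (0 gives identical cells).
#' @param abundance_shape Gamma shape for gene relative abundances; small
#'   values give a heavy-tailed abundance profile.
#' @param phi Global NB dispersion (Var = mu + mu^2/phi).
#' @param phi_sdlog Log-scale standard deviation of gene-wise dispersions
#'   (`nb_genewise` only).
#' @param zero_inflation_pi Structural-zero probability in \[0, 1\]; must be
#'   supplied for `model = "zinb"` and omitted otherwise.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return A list with `counts` (a [umi_counts()]) and `truth`: `pi`
#'   (per-gene abundances, summing to 1), `phi` or `phi_gene`, `libsize`
#'   (the drawn s_c), `model`, and `zero_inflation_pi` (zinb only).
#' @export
#' @examples
#' sim <- simulate_counts(50, 100, model = "nb", phi = 1, seed = 1)
#' sum(sim$truth$pi)
simulate_counts <- function(n_genes, n_cells,
                            model = c("poisson", "binomial", "nb",
                                      "nb_genewise", "zinb"),
                            mean_library_size = 5000, libsize_cv = 0.3,
                            abundance_shape = 1, phi = 1, phi_sdlog = 0.5,
                            zero_inflation_pi = NULL, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_genes >= 1, n_cells >= 1, mean_library_size > 0,
            libsize_cv >= 0, abundance_shape > 0, phi > 0)
  if (model == "zinb") {
    if (is.null(zero_inflation_pi))
      stop("model 'zinb' requires 'zero_inflation_pi'")
    if (zero_inflation_pi < 0 || zero_inflation_pi > 1)
      stop("'zero_inflation_pi' must be in [0, 1]")
  } else if (!is.null(zero_inflation_pi)) {
    stop("'zero_inflation_pi' is only meaningful for model 'zinb'")
  }
  set.seed(seed)

  sdlog <- sqrt(log(1 + libsize_cv^2))
  s <- if (libsize_cv > 0)
    stats::rlnorm(n_cells, meanlog = log(mean_library_size) - sdlog^2 / 2,
                  sdlog = sdlog)
  else rep(mean_library_size, n_cells)

  pi_g <- stats::rgamma(n_genes, shape = abundance_shape, rate = 1)
  pi_g <- pi_g / sum(pi_g)

  mu <- outer(pi_g, s)                       # genes x cells
  n <- n_genes * n_cells
  truth <- list(model = model, pi = pi_g, libsize = s)

  if (model == "binomial") {
    s_int <- pmax(1L, as.integer(round(s)))
    counts <- vapply(seq_len(n_cells),
                     function(c) stats::rmultinom(1, s_int[c], pi_g)[, 1],
                     integer(n_genes))
    counts <- matrix(counts, nrow = n_genes)
    truth$libsize <- s_int
  } else if (model == "poisson") {
    counts <- matrix(stats::rpois(n, as.vector(mu)), nrow = n_genes)
  } else if (model == "nb") {
    counts <- matrix(stats::rnbinom(n, size = phi, mu = as.vector(mu)),
                     nrow = n_genes)
    truth$phi <- phi
  } else if (model == "nb_genewise") {
    phi_g <- stats::rlnorm(n_genes, meanlog = log(phi), sdlog = phi_sdlog)
    # column-major fill: gene index cycles fastest, so size recycles per gene
    counts <- matrix(stats::rnbinom(n, size = phi_g, mu = as.vector(mu)),
                     nrow = n_genes)
    truth$phi_gene <- phi_g
  } else {                                   # zinb
    counts <- matrix(stats::rnbinom(n, size = phi, mu = as.vector(mu)),
                     nrow = n_genes)
    if (zero_inflation_pi > 0) {
      drop <- matrix(stats::rbinom(n, 1, zero_inflation_pi), nrow = n_genes)
      counts[drop == 1L] <- 0L
    }
    truth$phi <- phi
    truth$zero_inflation_pi <- zero_inflation_pi
  }

  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  barcodes <- sprintf("cell%04d", seq_len(n_cells))
  names(truth$pi) <- gene_ids
  names(truth$libsize) <- barcodes
  if (!is.null(truth$phi_gene)) names(truth$phi_gene) <- gene_ids
  list(counts = umi_counts(counts, gene_ids = gene_ids, barcodes = barcodes),
       truth = truth)
}

#' Simulate a small annotated genome with multi-isoform gene models
#'
#' Generates random chromosome sequences and a set of genes, each with one or
#' more isoforms. The first isoform of a gene uses all of the gene's exons;
#' additional isoforms are random exon subsets, so skipped exons create
#' intronic regions that are exonic in another isoform (the case that
#' separates the "collapse" and "separate" intron definitions). Optionally
#' inserts poly-A runs into intronic sequence, in the sense of the gene's
#' strand, to exercise internal-priming detection.
#'
#' @param n_chromosomes,n_genes Number of chromosomes and genes (genes are
#'   distributed round-robin).
#' @param isoforms_per_gene,exons_per_gene Integer ranges `c(lo, hi)` sampled
#'   per gene.
#' @param exon_length_range,intron_length_range Base-pair ranges sampled per
#'   exon/intron.
#' @param gc_content GC fraction of the background sequence, in (0, 1).
#' @param polyA_insert_prob Per-intron probability of inserting an A-run
#'   (written as T on the genome for minus-strand genes so the run reads as
#'   A in transcript orientation).
#' @param polyA_run_length Length of inserted runs; must not exceed the
#'   minimum intron length when `polyA_insert_prob > 0`.
#' @param chromosome_length Optional fixed chromosome length; an error is
#'   raised if the drawn genes do not fit. `NULL` sizes chromosomes to fit.
#' @param seed Integer seed.
#' @return A list with `models` (a [gene_model_set()]) and `genome` (named
#'   character vector of chromosome sequences).
#' @export
simulate_annotation <- function(n_chromosomes = 2, n_genes = 10,
                                isoforms_per_gene = c(1, 3),
                                exons_per_gene = c(1, 5),
                                exon_length_range = c(50, 300),
                                intron_length_range = c(100, 1000),
                                gc_content = 0.45,
                                polyA_insert_prob = 0,
                                polyA_run_length = 10,
                                chromosome_length = NULL, seed = 1) {
  stopifnot(n_chromosomes >= 1, n_genes >= 1,
            isoforms_per_gene[1] >= 1, exons_per_gene[1] >= 1,
            exon_length_range[1] >= 1, intron_length_range[1] >= 1,
            gc_content > 0, gc_content < 1,
            polyA_insert_prob >= 0, polyA_insert_prob <= 1,
            polyA_run_length >= 1)
  if (polyA_insert_prob > 0 && polyA_run_length > intron_length_range[1])
    stop("'polyA_run_length' exceeds the minimum intron length")
  set.seed(seed)

  rint <- function(range) if (range[1] == range[2]) range[1] else
    sample(range[1]:range[2], 1)

  chrom_of <- rep_len(seq_len(n_chromosomes), n_genes)
  offsets <- rep(100L, n_chromosomes)        # 5' margin per chromosome
  genes <- list()
  polyA_edits <- list()                      # chrom, start0, len, strand

  for (i in seq_len(n_genes)) {
    gid <- sprintf("gene%03d", i)
    chrom <- sprintf("chr%d", chrom_of[i])
    strand <- sample(c("+", "-"), 1)
    n_ex <- rint(exons_per_gene)
    ex_len <- vapply(seq_len(n_ex), function(k) rint(exon_length_range),
                     integer(1))
    in_len <- if (n_ex > 1)
      vapply(seq_len(n_ex - 1), function(k) rint(intron_length_range),
             integer(1)) else integer(0)
    start0 <- offsets[chrom_of[i]]
    starts <- start0 + cumsum(c(0L, utils::head(ex_len, -1) + in_len))
    ends <- starts + ex_len
    scaffold <- cbind(start = starts, end = ends)

    n_iso <- rint(isoforms_per_gene)
    txs <- list()
    txs[[sprintf("%s.t1", gid)]] <- scaffold
    if (n_iso > 1) for (j in 2:n_iso) {
      keep <- sort(sample(n_ex, rint(c(1, n_ex))))
      txs[[sprintf("%s.t%d", gid, j)]] <- scaffold[keep, , drop = FALSE]
    }
    genes[[gid]] <- list(chromosome = chrom, strand = strand,
                         transcripts = txs)

    if (polyA_insert_prob > 0 && n_ex > 1) {
      for (k in seq_len(n_ex - 1)) {
        if (stats::runif(1) < polyA_insert_prob) {
          gap <- c(ends[k], starts[k + 1])   # scaffold intron, half-open
          pos <- gap[1] + sample.int(gap[2] - gap[1] - polyA_run_length + 1L, 1) - 1L
          polyA_edits[[length(polyA_edits) + 1L]] <-
            list(chrom = chrom, start = pos, len = polyA_run_length,
                 strand = strand)
        }
      }
    }
    offsets[chrom_of[i]] <- max(ends) + 100L + sample.int(200L, 1)
  }

  chrom_len <- offsets + 100L
  if (!is.null(chromosome_length)) {
    if (any(chrom_len > chromosome_length))
      stop("requested gene lengths exceed chromosome size")
    chrom_len <- rep(chromosome_length, n_chromosomes)
  }
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
             (1 - gc_content) / 2)
  genome <- stats::setNames(vapply(chrom_len, function(L)
    paste(sample(bases, L, replace = TRUE, prob = probs), collapse = ""),
    character(1)), sprintf("chr%d", seq_len(n_chromosomes)))

  for (e in polyA_edits) {
    run <- strrep(if (e$strand == "+") "A" else "T", e$len)
    substr(genome[[e$chrom]], e$start + 1L, e$start + e$len) <- run
  }

  list(models = gene_model_set(genes), genome = genome)
}

#' Simulate per-gene totals with a log-linear length effect
#'
#' Gene lengths are drawn log-uniform over `length_range`; totals follow
#' log10(total + 1) = alpha + beta * log10(length) + Normal(0, sigma),
#' rounded to integers. Used to calibrate the length-bias estimators against
#' a known effect size.
#'
#' @param n_genes Number of genes.
#' @param beta Slope of the log10-log10 length effect.
#' @param sigma Standard deviation of the log10-scale noise (>= 0).
#' @param length_range Base-pair range `c(lo, hi)` for gene lengths.
#' @param alpha Intercept on the log10(total + 1) scale.
#' @param seed Integer seed.
#' @return A data.frame with `gene_id`, `length`, `total`.
#' @export
simulate_length_bias_totals <- function(n_genes, beta, sigma,
                                        length_range = c(500, 1e5),
                                        alpha = 1, seed = 1) {
  stopifnot(is.finite(beta), sigma >= 0, n_genes >= 1,
            length_range[1] > 0, length_range[2] >= length_range[1])
  set.seed(seed)
  len <- round(10^stats::runif(n_genes, log10(length_range[1]),
                               log10(length_range[2])))
  y <- alpha + beta * log10(len) + stats::rnorm(n_genes, 0, sigma)
  total <- pmax(round(10^y - 1), 0)
  data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
             length = as.integer(len), total = as.integer(total),
             stringsAsFactors = FALSE)
}

#' Simulate a labeled mixture of cell types with marker genes
#'
#' Each cell type has a set of marker genes whose relative abundance is
#' `fold_change` times the baseline in cells of that type; all other genes
#' share a common baseline profile. Counts are Poisson with lognormal
#' per-cell size factors.
#'
#' @param n_types Number of cell types.
#' @param markers_per_type Marker genes per type.
#' @param fold_change Marker enrichment in the own type (>= 1).
#' @param n_cells_per_type Cells per type.
#' @param n_noise_genes Non-marker background genes.
#' @param mean_library_size,libsize_cv Size-factor distribution, as in
#'   [simulate_counts()].
#' @param seed Integer seed.
#' @return A list with `counts` (a labeled [umi_counts()]), `labels` (named
#'   character vector, one per cell), `markers` (data.frame `celltype`,
#'   `gene_id`), and `profiles` (gene-by-type matrix of true relative
#'   abundances, usable as annotation reference profiles).
#' @export
simulate_celltype_mixture <- function(n_types = 3, markers_per_type = 10,
                                      fold_change = 10, n_cells_per_type = 100,
                                      n_noise_genes = 100,
                                      mean_library_size = 2000,
                                      libsize_cv = 0.3, seed = 1) {
  stopifnot(n_types >= 2, markers_per_type >= 1, fold_change >= 1,
            n_cells_per_type >= 1)
  set.seed(seed)
  n_genes <- n_types * markers_per_type + n_noise_genes
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  types <- sprintf("type%d", seq_len(n_types))
  marker_idx <- split(seq_len(n_types * markers_per_type),
                      rep(seq_len(n_types), each = markers_per_type))
  markers <- data.frame(
    celltype = rep(types, each = markers_per_type),
    gene_id = gene_ids[seq_len(n_types * markers_per_type)],
    stringsAsFactors = FALSE)

  base <- stats::rgamma(n_genes, shape = 2, rate = 1)
  profiles <- vapply(seq_len(n_types), function(t) {
    p <- base
    p[marker_idx[[t]]] <- p[marker_idx[[t]]] * fold_change
    p / sum(p)
  }, numeric(n_genes))
  dimnames(profiles) <- list(gene_ids, types)

  n_cells <- n_types * n_cells_per_type
  labels <- rep(types, each = n_cells_per_type)
  sdlog <- sqrt(log(1 + libsize_cv^2))
  s <- if (libsize_cv > 0)
    stats::rlnorm(n_cells, log(mean_library_size) - sdlog^2 / 2, sdlog)
  else rep(mean_library_size, n_cells)
  mu <- profiles[, labels] * rep(s, each = n_genes)
  counts <- matrix(stats::rpois(n_genes * n_cells, as.vector(mu)),
                   nrow = n_genes)
  barcodes <- sprintf("cell%04d", seq_len(n_cells))
  names(labels) <- barcodes
  list(counts = umi_counts(counts, gene_ids = gene_ids, barcodes = barcodes,
                           labels = labels),
       labels = labels, markers = markers, profiles = profiles)
}
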