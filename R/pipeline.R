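#' Default demo pipeline configuration
#'
#' A self-contained configuration that simulates NB counts and a small
#' annotated genome, runs QC, the distribution comparison, the length-bias
#' analysis and the cell-type annotation, writing everything under
#' `out_dir`. All stage parameters can be overridden by passing a partial
#' configuration to [run_pipeline()]; all randomness derives from the
#' single `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Root seed; each stage uses a fixed offset from it.
#' @return A nested list understood by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("nucdist_demo_"), seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    stages = c("simulate_counts", "simulate_annotation", "qc", "fit_dist",
               "length_bias", "celltype"),
    simulate_counts = list(n_genes = 200, n_cells = 300, model = "nb",
                           phi = 1, mean_library_size = 2000,
                           libsize_cv = 0.3, abundance_shape = 2),
    simulate_annotation = list(n_chromosomes = 2, n_genes = 200,
                               isoforms_per_gene = c(1, 3),
                               exons_per_gene = c(1, 6),
                               exon_length_range = c(50, 300),
                               intron_length_range = c(100, 2000),
                               polyA_insert_prob = 0.3,
                               polyA_run_length = 8),
    qc = list(min_library_size = 100, min_expressed_genes = 20,
              celltype = NULL),
    fit_dist = list(models = c("binomial", "poisson", "nb", "nb_genewise")),
    reference = list(kind = "preandmrna", flank_bp = 50),
    length_bias = list(n_bins = 10, polyA_n = 8),
    celltype = list(n_types = 3, markers_per_type = 10, fold_change = 10,
                    n_cells_per_type = 100, prune_delta = 0.05)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

stage_seed <- function(root, stage) {
  offsets <- c(simulate_counts = 101L, simulate_annotation = 211L,
               qc = 0L, fit_dist = 0L, length_bias = 307L, celltype = 401L)
  (as.integer(root) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the synthetic-data analysis pipeline
#'
#' Executes the configured stages in dependency order: simulation (counts
#' and annotation) feeds QC, which feeds the distribution comparison; the
#' annotation and counts feed the length-bias analysis; the cell-type stage
#' runs on its own labeled mixture. Each stage logs to stderr and writes
#' its outputs under the configured directory; a manifest records
#' parameters, seeds and MD5 checksums of every output file, so re-running
#' an identical configuration reproduces identical files.
#'
#' @param config A configuration list (see [demo_config()]), a path to a
#'   YAML file holding one, or `NULL` for the full demo. Partial lists are
#'   completed from the demo defaults.
#' @return Invisibly, a list with `manifest` (also written as
#'   `manifest.json`) and `results` holding the in-memory stage products
#'   (`counts`, `qc`, `fit`, `annotation`, `reference`, `length_bias`,
#'   `celltype`).
#' @export
run_pipeline <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(demo_config(), config %||% list())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  t0 <- Sys.time()
  log_stage <- function(stage, msg = "done")
    message(sprintf("[nucdist %6.1fs] %s: %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    stage, msg))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  for (stage in config$stages) {
    if (stage == "simulate_counts") {
      p <- config$simulate_counts
      results$counts <- run_stage(stage, do.call(simulate_counts,
        c(p, list(seed = stage_seed(config$seed, stage)))))
      d <- file.path(config$out_dir, "counts")
      write_10x_counts(results$counts$counts, d)
      jsonlite::write_json(results$counts$truth,
                           file.path(d, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    } else if (stage == "simulate_annotation") {
      p <- config$simulate_annotation
      results$annotation <- run_stage(stage, do.call(simulate_annotation,
        c(p, list(seed = stage_seed(config$seed, stage)))))
      write_gtf_models(results$annotation$models,
                       file.path(config$out_dir, "annotation.gtf"))
      write_genome_fasta(results$annotation$genome,
                         file.path(config$out_dir, "genome.fa"))
      rp <- config$reference
      results$reference <- run_stage(stage, build_reference(
        results$annotation$models, results$annotation$genome,
        kind = rp$kind, flank_bp = rp$flank_bp))
      write_reference(results$reference,
                      file.path(config$out_dir, "reference"))
    } else if (stage == "qc") {
      if (is.null(results$counts)) stop("stage 'qc': no counts available")
      p <- config$qc
      results$qc <- run_stage(stage, qc_pipeline(
        results$counts$counts, p$min_library_size, p$min_expressed_genes,
        p$celltype))
      write_10x_counts(results$qc, file.path(config$out_dir, "qc"))
    } else if (stage == "fit_dist") {
      m <- results$qc %||% results$counts$counts
      if (is.null(m)) stop("stage 'fit_dist': no counts available")
      results$fit <- run_stage(stage,
        fit_count_models(m, models = config$fit_dist$models))
      utils::write.table(results$fit$summaries,
                         file.path(config$out_dir, "gene_summaries.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(results$fit$bic,
                           file.path(config$out_dir, "model_comparison.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      utils::write.table(results$fit$gof$stats,
                         file.path(config$out_dir, "poisson_gof.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (stage == "length_bias") {
      if (is.null(results$annotation))
        stop("stage 'length_bias': no annotation available")
      m <- results$counts$counts
      if (is.null(m)) stop("stage 'length_bias': no counts available")
      # count matrix genes map onto the synthetic annotation's genes by rank
      gids <- names(results$annotation$models$genes)
      k <- min(nrow(m$counts), length(gids))
      m2 <- subset_counts(m, genes = seq_len(k))
      rownames(m2$counts) <- gids[seq_len(k)]
      p <- config$length_bias
      results$length_bias <- run_stage(stage, length_bias_analysis(
        m2, results$annotation$models, results$annotation$genome,
        n_bins = p$n_bins, polyA_n = p$polyA_n))
      utils::write.table(results$length_bias$per_gene,
                         file.path(config$out_dir, "length_bias_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(results$length_bias$per_bin,
                         file.path(config$out_dir, "length_bias_bins.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(preandmrna = results$length_bias$correlations$preandmrna,
             transcript = results$length_bias$correlations$transcript),
        file.path(config$out_dir, "length_correlations.json"),
        auto_unbox = TRUE, digits = NA)
    } else if (stage == "celltype") {
      p <- config$celltype
      mix <- run_stage(stage, simulate_celltype_mixture(
        n_types = p$n_types, markers_per_type = p$markers_per_type,
        fold_change = p$fold_change, n_cells_per_type = p$n_cells_per_type,
        seed = stage_seed(config$seed, stage)))
      assigned <- run_stage(stage, spearman_annotate(
        mix$counts, mix$profiles, mix$markers, prune_delta = p$prune_delta))
      results$celltype <- list(
        mixture = mix, assigned = assigned,
        concordance = concordance(mix$labels, assigned),
        accuracy = annotation_accuracy(mix$labels, assigned))
      utils::write.table(as.data.frame(results$celltype$concordance),
                         file.path(config$out_dir, "concordance.tsv"),
                         sep = "\t", quote = FALSE)
    } else {
      stop("unknown pipeline stage: ", stage)
    }
    log_stage(stage)
  }

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = config$seed, stages = config$stages,
    parameters = config[setdiff(names(config),
                                c("out_dir", "seed", "stages"))],
    checksums = as.list(tools::md5sum(sort(files))))
  names(manifest$checksums) <-
    sub(paste0("^", config$out_dir, "/?"), "", names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = results,
                 out_dir = config$out_dir))
}

#' Render a summary report from a pipeline run
#'
#' Writes `report.pdf` (mean-variance, zero-fraction, BIC and QQ panels
#' plus the length-bias panels) and `report.md` (the BIC ranking table and
#' headline numbers) into the run's output directory.
#'
#' @param run The list returned by [run_pipeline()].
#' @return Path to `report.md`, invisibly.
#' @export
demo_report <- function(run) {
  missing <- setdiff(c("fit", "length_bias"), names(run$results))
  if (length(missing))
    stop("missing pipeline outputs: ", paste(missing, collapse = ", "),
         " (run the fit_dist and length_bias stages first)")
  fit <- run$results$fit
  lb <- run$results$length_bias

  pdf_path <- file.path(run$out_dir, "report.pdf")
  grDevices::pdf(pdf_path, width = 12, height = 4)
  plot(fit)
  plot(lb)
  grDevices::dev.off()

  bic <- fit$bic
  lines <- c(
    "# nucdist pipeline report", "",
    sprintf("Matrix: %d genes x %d cells", fit$dim[1], fit$dim[2]), "",
    "## Model comparison (BIC, best first)", "",
    "| model | loglik | n_params | BIC | dBIC |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.2f | %d | %.2f | %.2f |", bic$model, bic$loglik,
            bic$n_params, bic$bic, bic$delta_bic),
    "",
    sprintf("Best model by BIC: **%s**", bic$model[1]), "",
    "## Length bias", "",
    sprintf("Pearson r (log10 scale): %.3f vs preandmrna length, %.3f vs transcript length",
            lb$correlations$preandmrna$r, lb$correlations$transcript$r),
    sprintf("Genes with internal poly-A: %d of %d",
            sum(lb$per_gene$has_polyA), nrow(lb$per_gene)))
  if (!is.null(run$results$celltype))
    lines <- c(lines, "", "## Cell-type annotation", "",
               sprintf("Accuracy vs simulated truth: %.3f",
                       run$results$celltype$accuracy))
  md_path <- file.path(run$out_dir, "report.md")
  writeLines(lines, md_path)
  invisible(md_path)
}
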