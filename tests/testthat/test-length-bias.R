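test_that("gene lengths use span and exon-sum, summarized by the max isoform", {
  m <- toy_models(list(t1 = cbind(c(0, 6), c(3, 9))))
  lens <- gene_lengths(m)
  expect_equal(lens$preandmrna_length, 9)
  expect_equal(lens$transcript_length, 6)

  single <- toy_models(list(t1 = cbind(5, 12)))
  lens1 <- gene_lengths(single)
  expect_equal(lens1$preandmrna_length, lens1$transcript_length)

  two <- toy_models(list(t1 = cbind(c(0, 6), c(3, 9)),      # spliced 6
                         t2 = cbind(c(0, 4), c(3, 9))))     # spliced 8
  expect_equal(gene_lengths(two)$transcript_length, 8)
  expect_equal(gene_lengths(two)$preandmrna_length, 9)
})

test_that("total gene counts are row sums, invariant to cell order", {
  m <- toy_counts(matrix(c(1, 2, 0, 0), 2, byrow = TRUE))
  expect_equal(unname(total_gene_counts(m)), c(3, 0))
  single <- toy_counts(matrix(c(4, 7), 2, 1))
  expect_equal(unname(total_gene_counts(single)), c(4, 7))
  perm <- subset_counts(m, cells = 2:1)
  expect_equal(total_gene_counts(perm), total_gene_counts(m))
})

test_that("equal-count binning is balanced, ascending and deterministic", {
  l10 <- setNames(10 * (10:1), sprintf("g%02d", 1:10))
  b10 <- bin_by_length(l10, 10)
  expect_equal(unname(b10[order(l10)]), 1:10)
  expect_equal(unname(b10["g10"]), 1)      # shortest gene in bin 1

  l11 <- setNames(c(l10, g11 = 5), c(names(l10), "g11"))
  b11 <- bin_by_length(l11, 10)
  expect_true(all(diff(range(table(b11))) <= 1))

  ties <- setNames(rep(7, 6), sprintf("g%d", c(3, 1, 2, 6, 5, 4)))
  t1 <- bin_by_length(ties, 3)
  expect_equal(t1[order(names(t1))],
               setNames(c(1, 1, 2, 2, 3, 3), sprintf("g%d", 1:6)))
  expect_identical(bin_by_length(ties, 3), t1)

  expect_error(bin_by_length(l10, 0), ">= 1")
  expect_error(bin_by_length(l10, 11), "exceeds")
})

test_that("bin summaries reproduce brute-force type-7 quantiles", {
  tot <- c(1, 2, 3)
  bs <- bin_summary(tot, rep(1, 3))
  expect_equal(bs$q25, 1.5)
  expect_equal(bs$median, 2)
  expect_equal(bs$q75, 2.5)

  const <- bin_summary(rep(4, 5), rep(1, 5))
  expect_true(all(c(const$q25, const$median, const$q75) == 4))

  set.seed(1)
  for (i in 1:20) {
    v <- sample(0:1000, sample(3:30, 1), replace = TRUE)
    bs <- bin_summary(v, rep(1, length(v)))
    expect_equal(bs$q25, oracle_quantile7(v, 0.25))
    expect_equal(bs$median, oracle_quantile7(v, 0.5))
    expect_equal(bs$q75, oracle_quantile7(v, 0.75))
  }

  # a huge top outlier moves q75 but not the median (n = 4: q75
  # interpolates between the 3rd and 4th order statistics)
  base <- c(1, 2, 3, 4)
  with_outlier <- c(1, 2, 3, 1e6)
  expect_equal(bin_summary(with_outlier, rep(1, 4))$median,
               bin_summary(base, rep(1, 4))$median)
  expect_gt(bin_summary(with_outlier, rep(1, 4))$q75,
            bin_summary(base, rep(1, 4))$q75)
  expect_equal(bin_summary(with_outlier, rep(1, 4))$q75,
               oracle_quantile7(with_outlier, 0.75))

  # invariant to within-bin ordering
  set.seed(2)
  v <- rpois(40, 20); b <- rep(1:4, each = 10)
  p <- sample(40)
  expect_equal(bin_summary(v[p], b[p]), bin_summary(v, b))

  expect_error(bin_summary(1:3, c(1, NA, 2)), "empty bin")
})

test_that("poly-A counting uses the maximal-run convention", {
  expect_equal(polyA_nmer_count("AAAA", 4), 1)
  expect_equal(polyA_nmer_count("AAACAAAA", 4), 1)
  expect_equal(polyA_nmer_count("AAAAAAAA", 4), 1)
  expect_equal(oracle_polyA_windows("AAAAAAAA", 4), 5)   # convention differs
  expect_equal(polyA_nmer_count("CGTCGT", 2), 0)
  expect_equal(polyA_nmer_count("aaaa", 4), 1)           # case-insensitive
  expect_equal(polyA_nmer_count("AACAA", 2), 2)

  set.seed(3)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                      prob = c(0.5, 0.2, 0.2, 0.1)), collapse = "")
    for (n in c(2, 4, 6))
      expect_identical(polyA_nmer_count(s, n), oracle_polyA_runs(s, n))
  }
})

test_that("gene-level poly-A max covers spliced and unspliced transcripts", {
  # intron carries the run: only the unspliced sequence sees it
  genome <- c(chr1 = paste0("CCCGGG", strrep("A", 8), "GGGCCC"))
  m <- toy_models(list(t1 = cbind(c(0, 14), c(6, 18))))
  sp <- spliced_transcript_sequences(m, genome)
  un <- unspliced_transcript_sequences(m, genome)
  expect_equal(polyA_nmer_count(sp$sequence, 8), 0)
  expect_equal(polyA_nmer_count(un$sequence, 8), 1)
  pa <- gene_polyA_max(m, genome, n = 8)
  expect_equal(pa$polyA_max, 1)
  expect_true(pa$has_polyA)

  none <- gene_polyA_max(m, c(chr1 = strrep("CG", 10)), n = 6)
  expect_equal(none$polyA_max, 0)
  expect_false(none$has_polyA)

  # splicing can join A-tracts across an exon junction: the spliced
  # sequence then carries a run the unspliced one does not
  genome2 <- c(chr1 = paste0("GGAAAA", "CCCCCC", "AAAAGG"))
  m2 <- toy_models(list(t1 = cbind(c(0, 12), c(6, 18))))
  sp2 <- spliced_transcript_sequences(m2, genome2)$sequence
  un2 <- unspliced_transcript_sequences(m2, genome2)$sequence
  expect_equal(polyA_nmer_count(sp2, 8), 1)
  expect_equal(polyA_nmer_count(un2, 8), 0)
  expect_equal(gene_polyA_max(m2, genome2, n = 8)$polyA_max, 1)
  expect_identical(polyA_nmer_count(sp2, 8), oracle_polyA_runs(sp2, 8))
})

test_that("log-scale length correlation matches exact and null cases", {
  len <- round(10^runif(50, 3, 5))
  exact <- log_length_correlation(len * 10, len)
  expect_equal(exact$r, 1, tolerance = 1e-12)

  set.seed(4)
  lens <- round(10^runif(2000, 3, 5))
  tot <- sample(round(10^runif(2000, 1, 3)))
  null <- log_length_correlation(tot, lens)
  expect_lt(abs(null$r), 0.1)

  expect_error(log_length_correlation(c(0, 0, 1, 2), c(1, 2, 3, 4)),
               "fewer than 3")
  zero_mix <- log_length_correlation(c(0, 10, 20, 40), c(1, 10, 20, 40))
  expect_equal(zero_mix$n_zero_excluded, 1)
  expect_equal(zero_mix$n_used, 3)
})

test_that("the loess trend reproduces linear and constant signals", {
  sim <- simulate_length_bias_totals(500, beta = 0.8, sigma = 0,
                                     length_range = c(1000, 1e5), seed = 9)
  tc <- trend_curve(sim$length, sim$total, span = 0.75)
  pred_line <- 1 + 0.8 * tc$log10_length     # alpha + beta * log10 L
  # totals are rounded to integers, so allow rounding-level slack
  expect_lt(max(abs(tc$log10_total - pred_line)), 0.01)

  const <- suppressWarnings(
    trend_curve(rep(c(1000, 2000, 4000, 8000), 5), rep(99, 20)))
  expect_true(all(abs(const$log10_total - log10(99)) < 1e-9))

  expect_error(trend_curve(1:20, rep(1, 20), span = 0), "span")
  expect_error(trend_curve(1:5, rep(1, 5)), "at least 10")
})

test_that("injected poly-A bonus lifts the trend only for poly-A genes", {
  sim <- simulate_length_bias_totals(1500, beta = 0.5, sigma = 0.2, seed = 10)
  set.seed(77)   # mask seed independent of the length-draw seed
  has_pa <- rbinom(1500, 1, 0.4) == 1
  bonus <- ifelse(has_pa, 10^0.4, 1)          # poly-A genes get extra counts
  tot <- round(sim$total * bonus)
  tc_pa <- trend_curve(sim$length[has_pa], tot[has_pa])
  tc_no <- trend_curve(sim$length[!has_pa], tot[!has_pa])
  grid <- seq(max(min(tc_pa$log10_length), min(tc_no$log10_length)) + 0.1,
              min(max(tc_pa$log10_length), max(tc_no$log10_length)) - 0.1,
              length.out = 20)
  f_pa <- approx(tc_pa$log10_length, tc_pa$log10_total, grid)$y
  f_no <- approx(tc_no$log10_length, tc_no$log10_total, grid)$y
  expect_true(all(f_pa > f_no))

  # without the bonus the two trends coincide within noise
  tc_pa0 <- trend_curve(sim$length[has_pa], sim$total[has_pa])
  tc_no0 <- trend_curve(sim$length[!has_pa], sim$total[!has_pa])
  g_pa <- approx(tc_pa0$log10_length, tc_pa0$log10_total, grid)$y
  g_no <- approx(tc_no0$log10_length, tc_no0$log10_total, grid)$y
  expect_lt(max(abs(g_pa - g_no)), 0.1)

  # residual bias: the non-poly-A subgroup alone still shows r > 0
  r_no <- log_length_correlation(tot[!has_pa], sim$length[!has_pa])$r
  n_no <- sum(!has_pa & tot > 0)
  expect_gt(r_no, 2 / sqrt(n_no))            # clearly above the null band
})

test_that("the combined length-bias analysis ties the pieces together", {
  sim <- simulate_annotation(n_genes = 60, isoforms_per_gene = c(1, 3),
                             exons_per_gene = c(1, 5),
                             polyA_insert_prob = 0.5, polyA_run_length = 8,
                             seed = 11)
  cnt <- simulate_counts(60, 100, model = "poisson", seed = 11)$counts
  rownames(cnt$counts) <- names(sim$models$genes)
  lb <- length_bias_analysis(cnt, sim$models, sim$genome, n_bins = 6,
                             polyA_n = 8)
  expect_s3_class(lb, "length_bias")
  expect_equal(nrow(lb$per_gene), 60)
  expect_true(all(lb$per_gene$preandmrna_length >=
                    lb$per_gene$transcript_length))
  expect_true(all(diff(range(table(lb$per_gene$bin_id))) <= 1))
  expect_true(all(lb$per_bin$q25 <= lb$per_bin$median &
                    lb$per_bin$median <= lb$per_bin$q75))
  pdf(NULL); expect_invisible(plot(lb)); dev.off()
})
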