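test_that("gene summaries follow hand arithmetic", {
  m <- toy_counts(matrix(c(1, 1, 1, 1,
                           0, 0, 2, 2,
                           0, 0, 0, 0), nrow = 3, byrow = TRUE))
  gs <- gene_summaries(m)
  expect_equal(gs$mean, c(1, 1, 0))
  expect_equal(gs$variance, c(0, 4 / 3, 0))
  expect_equal(gs$zero_fraction, c(0, 0.5, 1))
  expect_error(gene_summaries(toy_counts(matrix(1, 2, 1))), "2 cells")
})

test_that("abundance estimates are normalized row shares", {
  m <- toy_counts(matrix(1, 2, 2))
  expect_equal(unname(estimate_abundance(m)), c(0.5, 0.5))
  one <- toy_counts(matrix(c(3, 4), 1))
  expect_equal(unname(estimate_abundance(one)), 1)
  m2 <- toy_counts(matrix(c(1, 2, 3, 4), 2))
  expect_equal(estimate_abundance(m2),
               estimate_abundance(toy_counts(5 * matrix(c(1, 2, 3, 4), 2))))
  expect_error(estimate_abundance(toy_counts(matrix(0, 2, 2))), "zero total")
})

test_that("poisson log-likelihood matches the closed form on a unit matrix", {
  m <- toy_counts(matrix(1, 2, 2))
  fit <- fit_model(m, "poisson")
  expect_equal(fit$loglik_total, -4)            # 4 * log(exp(-1) * 1^1 / 1!)
  expect_equal(fit$n_params, 2)
  expect_equal(fit$n_obs, 4)
  expect_equal(fit$bic, 2 * log(4) + 8)
})

test_that("global NB fit degenerates to Poisson on Poisson data", {
  sim <- simulate_counts(200, 500, model = "poisson", seed = 41)
  pois <- fit_model(sim$counts, "poisson")
  nb <- fit_model(sim$counts, "nb_global")
  expect_true(nb$phi_global > 1e6 ||
                abs(nb$loglik_total - pois$loglik_total) < 0.1)
})

test_that("global NB fit recovers the simulated dispersion", {
  sim <- simulate_counts(500, 1000, model = "nb", phi = 1, seed = 42)
  fit <- fit_model(sim$counts, "nb_global")
  expect_gt(fit$phi_global, 0.8)
  expect_lt(fit$phi_global, 1.2)
})

test_that("likelihoods are nested: genewise >= global >= fixed phi", {
  for (seed in c(7, 8)) {
    sim <- simulate_counts(60, 150, model = "nb", phi = 0.6, seed = seed)
    global <- fit_model(sim$counts, "nb_global")
    genewise <- fit_model(sim$counts, "nb_genewise")
    expect_gte(genewise$loglik_total, global$loglik_total - 1e-6)
    x <- as.matrix(sim$counts$counts)
    mu <- outer(estimate_abundance(sim$counts), library_sizes(sim$counts))
    for (phi_fixed in c(0.2, 1, 5)) {
      ll_fixed <- sum(dnbinom(x, size = phi_fixed, mu = mu, log = TRUE))
      expect_gte(global$loglik_total, ll_fixed - 1e-6)
    }
  }
})

test_that("NB log-likelihood approaches Poisson as phi grows", {
  sim <- simulate_counts(100, 200, model = "poisson", seed = 43)
  x <- as.matrix(sim$counts$counts)
  mu <- outer(estimate_abundance(sim$counts), library_sizes(sim$counts))
  ll_nb <- sum(dnbinom(x, size = 1e8, mu = mu, log = TRUE))
  ll_pois <- sum(dpois(x, mu, log = TRUE))
  expect_lt(abs(ll_nb - ll_pois), 1e-3 * length(x) / 1e5 + 1e-3)
})

test_that("zero-variance genes get the dispersion upper bound with warning", {
  m <- toy_counts(rbind(rep(2, 6), c(0, 1, 5, 0, 2, 9)))
  expect_warning(fit <- fit_model(m, "nb_genewise"), "zero variance")
  expect_equal(unname(fit$phi_gene[1]), 1e8)
})

test_that("expected variance follows each model's law", {
  expect_equal(expected_variance("nb", 2, phi = 1), 6)
  expect_equal(expected_variance("nb", 3, phi = 1e12), 3, tolerance = 1e-6)
  expect_equal(expected_variance("poisson", 0), 0)
  expect_equal(expected_variance("nb", 0, phi = 2), 0)
  expect_equal(expected_variance("binomial", 0, mean_libsize = 10), 0)
  expect_equal(expected_variance("poisson", c(1, 5)), c(1, 5))
  expect_equal(expected_variance("binomial", 2, mean_libsize = 8),
               2 * (1 - 2 / 8))
  expect_error(expected_variance("nb", 1, phi = -1))
  expect_error(expected_variance("nb", 1))
})

test_that("expected zero fractions match closed forms and Monte Carlo", {
  for (model in c("poisson", "binomial", "nb"))
    expect_equal(expected_zero_fraction(model, 0, libsizes = c(5, 10),
                                        phi = 1), 1)
  expect_equal(expected_zero_fraction("poisson", 1, libsizes = 1), exp(-1))
  expect_equal(expected_zero_fraction("nb", 1, libsizes = 1, phi = 1), 0.5)
  set.seed(1)
  mc <- mean(rnbinom(1e5, size = 1, mu = 1) == 0)
  expect_equal(mc, 0.5, tolerance = 0.01)
  # averaged over heterogeneous cells
  s <- c(1, 2, 4)
  expect_equal(expected_zero_fraction("poisson", 0.5, libsizes = s),
               mean(exp(-0.5 * s)))
  expect_equal(expected_zero_fraction("binomial", 0.3, libsizes = c(2, 3)),
               mean(c(0.7^2, 0.7^3)))
})

test_that("bic_compare ranks by the BIC formula and validates inputs", {
  f1 <- structure(list(model = "poisson", loglik_total = 0, n_params = 1L,
                       n_obs = 1, bic = 1 * log(1) - 0),
                  class = "fit_result")
  expect_equal(bic_compare(list(f1))$bic, 0)

  sim <- simulate_counts(50, 100, model = "nb", phi = 1, seed = 45)
  fits <- lapply(c("poisson", "nb_global", "nb_genewise"),
                 function(mod) fit_model(sim$counts, mod))
  cmp <- bic_compare(fits)
  expect_equal(cmp$bic, sort(cmp$bic))
  expect_equal(cmp$delta_bic[1], 0)
  for (f in fits)
    expect_equal(f$bic, f$n_params * log(f$n_obs) - 2 * f$loglik_total)

  # equal loglik: fewer parameters wins
  fa <- structure(list(model = "a", loglik_total = -10, n_params = 5L,
                       n_obs = 100, bic = 5 * log(100) + 20),
                  class = "fit_result")
  fb <- structure(list(model = "b", loglik_total = -10, n_params = 10L,
                       n_obs = 100, bic = 10 * log(100) + 20),
                  class = "fit_result")
  expect_equal(bic_compare(list(fb, fa))$model[1], "a")

  f_other <- fit_model(simulate_counts(10, 10, seed = 1)$counts, "poisson")
  expect_error(bic_compare(list(fits[[1]], f_other)), "n_obs")
})

test_that("poisson GOF statistics follow hand arithmetic", {
  # counts equal to expectations exactly
  m <- toy_counts(matrix(c(2, 2, 1, 1), 2, byrow = TRUE))
  gof <- poisson_gof(m)
  expect_equal(gof$stats$pearson_stat, c(0, 0))
  expect_equal(gof$dof, 1)

  # equal library sizes, gene counts (0, 2) with mu-hat = 1
  m2 <- toy_counts(matrix(c(0, 2, 2, 0), 2, byrow = TRUE))
  gof2 <- poisson_gof(m2)
  expect_equal(gof2$stats$pearson_stat, c(2, 2))

  # zero-abundance genes are excluded and reported
  m3 <- toy_counts(matrix(c(1, 2, 0, 0), 2, byrow = TRUE))
  gof3 <- poisson_gof(m3)
  expect_equal(gof3$excluded, "g2")
  expect_equal(nrow(gof3$stats), 1)
  expect_equal(nrow(gof3$qq), 1)
})

test_that("fits and BIC are invariant to gene and cell permutations", {
  sim <- simulate_counts(40, 60, model = "nb", phi = 0.8, seed = 47)
  m <- sim$counts
  set.seed(1)
  mp <- subset_counts(m, genes = sample(nrow(m$counts)),
                      cells = sample(ncol(m$counts)))
  for (mod in c("poisson", "binomial", "nb_global")) {
    f1 <- fit_model(m, mod)
    f2 <- fit_model(mp, mod)
    expect_equal(f1$loglik_total, f2$loglik_total, tolerance = 1e-9)
    expect_equal(f1$bic, f2$bic, tolerance = 1e-9)
  }
})

test_that("zero-inflation flagging separates zinb from nb data", {
  # well-expressed regime: against a freely fitted NB dispersion, excess
  # zeros are only detectable where the zero probability is informative
  zi <- simulate_counts(150, 300, model = "zinb", phi = 1,
                        zero_inflation_pi = 0.3, abundance_shape = 5,
                        mean_library_size = 5000, seed = 48)
  res_zi <- detect_zero_inflation(zi$counts)
  nb <- simulate_counts(150, 300, model = "nb", phi = 1,
                        abundance_shape = 5,
                        mean_library_size = 5000, seed = 48)
  res_nb <- detect_zero_inflation(nb$counts)
  expect_gt(res_zi$excess_rate, res_nb$excess_rate + 0.2)
  expect_gt(res_zi$excess_rate, 0.8)
  expect_lt(res_nb$excess_rate, 0.7)
  # the zinb fit absorbs structural zeros into a smaller dispersion
  expect_lt(res_zi$phi, res_nb$phi)
})

test_that("the distfit object supports the standard model methods", {
  sim <- simulate_counts(40, 80, model = "nb", phi = 1, seed = 49)
  fit <- fit_count_models(sim$counts,
                          models = c("poisson", "nb", "nb_genewise"))
  expect_s3_class(fit, "distfit")
  expect_equal(fit$bic$model[1], "nb_global")

  s <- summary(fit)
  expect_s3_class(s, "summary.distfit")
  expect_output(print(s), "Best model by BIC")

  cf <- coef(fit, "nb_global")
  expect_equal(sum(cf$pi), 1, tolerance = 1e-12)
  expect_gt(cf$phi, 0)

  ll <- logLik(fit, "poisson")
  expect_equal(attr(ll, "df"), 40)
  expect_equal(attr(ll, "nobs"), 40 * 80)

  r <- residuals(fit, sim$counts, model = "nb_global")
  expect_equal(dim(r), c(40, 80))
  expect_lt(abs(mean(r)), 0.2)

  reps <- simulate(fit, nsim = 2, seed = 1, model = "nb_global")
  expect_length(reps, 2)
  expect_identical(dim(reps[[1]]$counts), c(40L, 80L))

  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()

  expect_error(fit_model(sim$counts, "gamma"), "unknown model")
})
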