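#' Per-gene empirical summaries
#'
#' For each gene: the empirical mean, the empirical (sample) variance with
#' denominator C - 1, and the observed fraction of zero counts across cells.
#' These are the raw quantities behind mean-variance and zero-fraction plots.
#'
#' @param m A [umi_counts()] object with at least 2 cells.
#' @return A data.frame with `gene_id`, `mean`, `variance`, `zero_fraction`.
#' @export
gene_summaries <- function(m) {
  stopifnot(inherits(m, "umi_counts"))
  C <- ncol(m$counts)
  if (C < 2) stop("need at least 2 cells for variances")
  mu <- Matrix::rowMeans(m$counts)
  ex2 <- Matrix::rowSums(m$counts^2)
  v <- (ex2 - C * mu^2) / (C - 1)
  zf <- Matrix::rowSums(m$counts == 0) / C
  data.frame(gene_id = rownames(m$counts), mean = mu,
             variance = pmax(v, 0), zero_fraction = zf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plug-in relative abundance estimates
#'
#' The multinomial plug-in estimate pi_g = (sum of gene g's counts) /
#' (grand total), shared by all four count models through the mean structure
#' mu_cg = s_c * pi_g. Abundances sum to one.
#'
#' @param m A [umi_counts()] object with positive grand total.
#' @return Named numeric vector of per-gene abundances.
#' @export
estimate_abundance <- function(m) {
  stopifnot(inherits(m, "umi_counts"))
  tot <- Matrix::rowSums(m$counts)
  grand <- sum(tot)
  if (grand <= 0) stop("count matrix has zero total")
  tot / grand
}

PHI_LOWER <- 1e-8
PHI_UPPER <- 1e8

model_names <- c("binomial", "poisson", "nb_global", "nb_genewise")

canonical_model <- function(model) {
  model <- gsub("-", "_", tolower(model))
  model[model == "nb"] <- "nb_global"
  if (!all(model %in% model_names))
    stop("unknown model(s): ", paste(setdiff(model, model_names), collapse = ", "),
         " (choose from ", paste(model_names, collapse = ", "), ")")
  model
}

# maximize sum(dnbinom(x, size = phi, mu = mu, log = TRUE)) over log(phi)
profile_phi <- function(x, mu, tol = 1e-6) {
  f <- function(lp) sum(stats::dnbinom(x, size = exp(lp), mu = mu, log = TRUE))
  opt <- stats::optimize(f, c(log(PHI_LOWER), log(PHI_UPPER)),
                         maximum = TRUE, tol = tol)
  list(phi = exp(opt$maximum), loglik = opt$objective)
}

#' Fit one count model to a UMI matrix
#'
#' All models share the mean structure mu_cg = s_c * pi_g with s_c the
#' observed library size and pi_g the plug-in abundance of
#' [estimate_abundance()]; only the dispersion is optimized, which keeps the
#' four models nested and their likelihoods comparable.
#'
#' \describe{
#'   \item{binomial}{X_cg ~ Binomial(s_c, pi_g); no free dispersion
#'     (G parameters, the abundances).}
#'   \item{poisson}{X_cg ~ Poisson(s_c pi_g) (G parameters).}
#'   \item{nb_global}{X_cg ~ NB(mu = s_c pi_g, dispersion phi) with
#'     Var = mu + mu^2/phi; one phi for the whole data set, estimated by
#'     1-D maximum likelihood over log(phi) in \[1e-8, 1e8\]
#'     (G + 1 parameters).}
#'   \item{nb_genewise}{Independent per-gene dispersions phi_g, each a 1-D
#'     MLE (2G parameters). Genes with zero empirical variance have a
#'     degenerate MLE and are set to the upper dispersion bound, with one
#'     warning.}
#' }
#'
#' @param m A [umi_counts()] object (after QC).
#' @param model Model name; `"nb"` is accepted for `"nb_global"`.
#' @return A list of class `fit_result`: `model`, `pi`, `phi_global`,
#'   `phi_gene`, `loglik_total`, `n_params`, `n_obs`, `bic`.
#' @export
#' @examples
#' sim <- simulate_counts(30, 60, model = "poisson", seed = 3)
#' fit_model(sim$counts, "poisson")$bic
fit_model <- function(m, model) {
  stopifnot(inherits(m, "umi_counts"))
  model <- canonical_model(model)
  stopifnot(length(model) == 1)
  x <- as.matrix(m$counts)
  s <- colSums(x)
  pi_g <- rowSums(x) / sum(x)
  mu <- outer(pi_g, s)
  G <- nrow(x); C <- ncol(x)
  n_obs <- G * C
  phi_global <- NULL; phi_gene <- NULL

  if (model == "binomial") {
    ll <- sum(stats::dbinom(x, size = rep(s, each = G), prob = pi_g,
                            log = TRUE))
    n_params <- G
  } else if (model == "poisson") {
    ll <- sum(stats::dpois(x, mu, log = TRUE))
    n_params <- G
  } else if (model == "nb_global") {
    opt <- profile_phi(as.vector(x), as.vector(mu))
    phi_global <- opt$phi
    ll <- opt$loglik
    n_params <- G + 1L
  } else {
    v <- apply(x, 1, stats::var)
    phi_gene <- numeric(G)
    ll_g <- numeric(G)
    degenerate <- v == 0
    for (g in which(!degenerate)) {
      opt <- profile_phi(x[g, ], mu[g, ])
      phi_gene[g] <- opt$phi
      ll_g[g] <- opt$loglik
    }
    if (any(degenerate)) {
      warning(sum(degenerate), " gene(s) with zero variance: dispersion set ",
              "to the upper bound")
      for (g in which(degenerate)) {
        phi_gene[g] <- PHI_UPPER
        ll_g[g] <- sum(stats::dnbinom(x[g, ], size = PHI_UPPER, mu = mu[g, ],
                                      log = TRUE))
      }
    }
    names(phi_gene) <- rownames(m$counts)
    ll <- sum(ll_g)
    n_params <- 2L * G
  }
  if (!is.finite(ll)) stop("non-finite log-likelihood for model ", model)
  structure(list(model = model, pi = stats::setNames(pi_g, rownames(m$counts)),
                 phi_global = phi_global, phi_gene = phi_gene,
                 loglik_total = ll, n_params = n_params, n_obs = n_obs,
                 bic = n_params * log(n_obs) - 2 * ll),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s | loglik %.2f | params %d | BIC %.2f\n",
              x$model, x$loglik_total, x$n_params, x$bic))
  if (!is.null(x$phi_global)) cat(sprintf("  phi = %.4g\n", x$phi_global))
  if (!is.null(x$phi_gene))
    cat(sprintf("  phi_g: median %.4g [%.4g, %.4g]\n",
                stats::median(x$phi_gene), min(x$phi_gene), max(x$phi_gene)))
  invisible(x)
}

#' Theoretical variance curves
#'
#' The variance each model implies at mean expression `mu`: Poisson
#' Var = mu; NB Var = mu + mu^2/phi; binomial Var = mu (1 - mu / s_bar)
#' with `mean_libsize` = s_bar, the display convention for a
#' mean-variance overlay.
#'
#' @param model `"poisson"`, `"nb"` (or `"nb_global"`/`"nb_genewise"`), or
#'   `"binomial"`.
#' @param mu Nonnegative mean(s).
#' @param phi NB dispersion (> 0); required for NB.
#' @param mean_libsize Mean library size; required for binomial.
#' @return Numeric vector of variances.
#' @export
expected_variance <- function(model, mu, phi = NULL, mean_libsize = NULL) {
  model <- canonical_model(model)
  stopifnot(all(mu >= 0))
  if (model == "poisson") return(mu)
  if (model %in% c("nb_global", "nb_genewise")) {
    if (is.null(phi) || any(phi <= 0)) stop("NB variance needs phi > 0")
    return(mu + mu^2 / phi)
  }
  if (is.null(mean_libsize) || mean_libsize <= 0)
    stop("binomial variance needs 'mean_libsize' > 0")
  mu * (1 - mu / mean_libsize)
}

#' Expected fraction of zero counts
#'
#' For gene g with abundance pi_g and cell library sizes s_c, the expected
#' zero fraction is the average over cells of the model's zero probability
#' at mu_cg = s_c pi_g: Poisson exp(-mu); binomial (1 - pi_g)^{s_c}; NB
#' (phi / (phi + mu))^phi.
#'
#' @param model `"poisson"`, `"binomial"`, or `"nb"`.
#' @param pi_g Gene abundance(s) in \[0, 1\] (vectorized over genes).
#' @param libsizes Positive per-cell library sizes.
#' @param phi NB dispersion (> 0); required for NB.
#' @return Numeric vector, one expected zero fraction per gene.
#' @export
#' @examples
#' expected_zero_fraction("nb", 1, libsizes = 1, phi = 1)  # 0.5
expected_zero_fraction <- function(model, pi_g, libsizes, phi = NULL) {
  model <- canonical_model(model)
  stopifnot(all(pi_g >= 0), all(pi_g <= 1), all(libsizes > 0))
  mu <- outer(pi_g, libsizes)                # genes x cells
  p0 <- if (model == "poisson") exp(-mu)
  else if (model == "binomial") outer(pi_g, libsizes,
                                      function(p, s) (1 - p)^s)
  else {
    if (is.null(phi) || phi <= 0) stop("NB zero fraction needs phi > 0")
    (phi / (phi + mu))^phi
  }
  rowMeans(p0)
}

#' Compare fitted models by BIC
#'
#' BIC = n_params * ln(n_obs) - 2 * loglik, with n_obs = G * C (genes are
#' treated as independent and every count is one observation). Lower is
#' better.
#'
#' @param fits List of [fit_model()] results on the same matrix.
#' @return A data.frame sorted ascending by BIC: `model`, `loglik`,
#'   `n_params`, `bic`, `delta_bic`.
#' @export
bic_compare <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "fit_result")))
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1)
    stop("fits come from matrices of different sizes (n_obs mismatch)")
  out <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik_total"),
    n_params = vapply(fits, `[[`, integer(1), "n_params"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    stringsAsFactors = FALSE)
  out <- out[order(out$bic), ]
  out$delta_bic <- out$bic - out$bic[1]
  rownames(out) <- NULL
  out
}

#' Pearson goodness-of-fit statistics under the Poisson model
#'
#' Per gene, the statistic sum_c (x_cg - mu_cg)^2 / mu_cg with
#' mu_cg = s_c * pi_g (plug-in abundances), compared against a chi-squared
#' distribution with C - 1 degrees of freedom (one abundance fitted per
#' gene). Genes with zero estimated abundance are excluded and reported.
#'
#' @param m A [umi_counts()] object.
#' @return A list of class `poisson_gof`: `stats` (data.frame `gene_id`,
#'   `pearson_stat`, `dof`), `dof`, `excluded` (gene ids with pi = 0),
#'   and `qq` (data.frame `theoretical`, `observed`): sorted statistics
#'   against chi-squared quantiles at plotting positions (i - 0.5) / G.
#' @export
poisson_gof <- function(m) {
  stopifnot(inherits(m, "umi_counts"))
  x <- as.matrix(m$counts)
  s <- colSums(x)
  pi_g <- rowSums(x) / sum(x)
  keep <- pi_g > 0
  excluded <- rownames(m$counts)[!keep]
  x <- x[keep, , drop = FALSE]
  mu <- outer(pi_g[keep], s)
  stat <- rowSums((x - mu)^2 / mu)
  dof <- ncol(x) - 1L
  G <- length(stat)
  qq <- data.frame(
    theoretical = stats::qchisq((seq_len(G) - 0.5) / G, df = dof),
    observed = sort(stat))
  structure(list(stats = data.frame(gene_id = rownames(x),
                                    pearson_stat = stat, dof = dof,
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 dof = dof, excluded = excluded, qq = qq),
            class = "poisson_gof")
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf("poisson_gof: %d genes, dof = %d; median stat %.1f (chi2 median %.1f)\n",
              nrow(x$stats), x$dof, stats::median(x$stats$pearson_stat),
              stats::qchisq(0.5, x$dof)))
  if (length(x$excluded))
    cat("  excluded (zero abundance):", length(x$excluded), "genes\n")
  invisible(x)
}

#' Flag zero inflation against the fitted negative binomial
#'
#' Compares each gene's observed zero fraction with the zero fraction
#' expected under the globally fitted NB (mu_cg = s_c pi_g, dispersion
#' phi-hat). Data are called zero-inflated in the operational sense when the
#' observed fraction systematically exceeds the NB expectation among
#' well-expressed genes; for NB-distributed data the exceedance rate sits
#' near one half.
#'
#' @param m A [umi_counts()] object.
#' @param fit Optional [fit_model()] result for `nb_global` on `m` (fitted
#'   here when `NULL`).
#' @param min_mean Genes with empirical mean above this enter the exceedance
#'   rate (low-expression genes carry little information about zeros).
#' @return A list: `table` (per-gene data.frame with `mean`,
#'   `observed_zero`, `expected_zero`, `excess`), `phi`, and
#'   `excess_rate` — the share of genes with mean > `min_mean` whose
#'   observed zero fraction exceeds the NB expectation.
#' @export
detect_zero_inflation <- function(m, fit = NULL, min_mean = 1) {
  stopifnot(inherits(m, "umi_counts"))
  if (is.null(fit)) fit <- fit_model(m, "nb_global")
  stopifnot(fit$model == "nb_global")
  gs <- gene_summaries(m)
  expected <- expected_zero_fraction("nb", fit$pi, library_sizes(m),
                                     phi = fit$phi_global)
  tab <- data.frame(gene_id = gs$gene_id, mean = gs$mean,
                    observed_zero = gs$zero_fraction,
                    expected_zero = expected,
                    excess = gs$zero_fraction > expected,
                    row.names = NULL, stringsAsFactors = FALSE)
  sel <- tab$mean > min_mean
  list(table = tab, phi = fit$phi_global,
       excess_rate = if (any(sel)) mean(tab$excess[sel]) else NA_real_)
}
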