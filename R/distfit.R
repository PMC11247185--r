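#' Fit and compare count distributions for a UMI matrix
#'
#' The package's central fitting function. Fits the requested count models
#' (see [fit_model()]) to a QC'd gene-by-cell UMI matrix, computes per-gene
#' empirical summaries and Poisson goodness-of-fit statistics, and ranks the
#' models by BIC. All models share the offset mean structure
#' mu_cg = s_c * pi_g, so BIC differences reflect only how each family
#' handles dispersion.
#'
#' @param m A [umi_counts()] object (after QC; see [qc_pipeline()]).
#' @param models Character vector of model names; `"nb"` means
#'   `"nb_global"`.
#' @param gof Compute the per-gene Poisson goodness-of-fit statistics
#'   (default `TRUE`).
#' @return An object of class `distfit`: list with `fits` (named
#'   [fit_model()] results), `summaries` ([gene_summaries()]), `bic`
#'   ([bic_compare()] table), `gof` ([poisson_gof()] or `NULL`),
#'   `libsizes`, and `dim`.
#' @seealso [plot.distfit()], [simulate.distfit()], [residuals.distfit()]
#' @export
#' @examples
#' sim <- simulate_counts(40, 80, model = "nb", phi = 1, seed = 5)
#' fit <- fit_count_models(sim$counts, models = c("poisson", "nb"))
#' summary(fit)
fit_count_models <- function(m, models = c("binomial", "poisson", "nb",
                                           "nb_genewise"), gof = TRUE) {
  stopifnot(inherits(m, "umi_counts"))
  models <- canonical_model(models)
  fits <- stats::setNames(lapply(models, function(mod) fit_model(m, mod)),
                          models)
  structure(list(fits = fits, summaries = gene_summaries(m),
                 bic = bic_compare(fits),
                 gof = if (gof) poisson_gof(m) else NULL,
                 libsizes = library_sizes(m), dim = dim(m$counts)),
            class = "distfit")
}

best_model <- function(object) object$bic$model[1]

#' @export
print.distfit <- function(x, ...) {
  cat(sprintf("distfit: %d genes x %d cells; models: %s\n",
              x$dim[1], x$dim[2], paste(names(x$fits), collapse = ", ")))
  cat(sprintf("best by BIC: %s\n", best_model(x)))
  print(x$bic, digits = 6)
  invisible(x)
}

#' @export
summary.distfit <- function(object, ...) {
  phi <- object$fits$nb_global$phi_global
  phi_gene <- object$fits$nb_genewise$phi_gene
  out <- list(dim = object$dim, bic = object$bic, best = best_model(object),
              phi_global = phi,
              phi_gene_quartiles = if (!is.null(phi_gene))
                stats::quantile(phi_gene, c(0.25, 0.5, 0.75)) else NULL,
              median_zero_fraction = stats::median(object$summaries$zero_fraction),
              gof_median = if (!is.null(object$gof))
                stats::median(object$gof$stats$pearson_stat) else NULL,
              gof_dof = object$gof$dof)
  class(out) <- "summary.distfit"
  out
}

#' @export
print.summary.distfit <- function(x, ...) {
  cat(sprintf("Count-distribution comparison on %d genes x %d cells\n",
              x$dim[1], x$dim[2]))
  cat(sprintf("Best model by BIC: %s\n\n", x$best))
  print(x$bic, digits = 6)
  if (!is.null(x$phi_global))
    cat(sprintf("\nGlobal NB dispersion phi = %.4g\n", x$phi_global))
  if (!is.null(x$phi_gene_quartiles))
    cat(sprintf("Gene-wise phi quartiles: %.3g / %.3g / %.3g\n",
                x$phi_gene_quartiles[1], x$phi_gene_quartiles[2],
                x$phi_gene_quartiles[3]))
  cat(sprintf("Median observed zero fraction: %.3f\n",
              x$median_zero_fraction))
  if (!is.null(x$gof_median))
    cat(sprintf("Median Poisson GOF statistic: %.1f (chi2 df = %d median %.1f)\n",
                x$gof_median, x$gof_dof, stats::qchisq(0.5, x$gof_dof)))
  invisible(x)
}

#' @export
coef.distfit <- function(object, model = NULL, ...) {
  model <- canonical_model(if (is.null(model)) best_model(object) else model)
  fit <- object$fits[[model]]
  if (is.null(fit)) stop("model '", model, "' was not fitted")
  list(pi = fit$pi, phi = fit$phi_global %||% fit$phi_gene)
}

#' @export
logLik.distfit <- function(object, model = NULL, ...) {
  model <- canonical_model(if (is.null(model)) best_model(object) else model)
  fit <- object$fits[[model]]
  if (is.null(fit)) stop("model '", model, "' was not fitted")
  structure(fit$loglik_total, df = fit$n_params, nobs = fit$n_obs,
            class = "logLik")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fitted_mu <- function(object, model) {
  fit <- object$fits[[model]]
  outer(fit$pi, object$libsizes)
}

#' Pearson residuals of a fitted count model
#'
#' (x - mu) / sqrt(V(mu)) with the model's variance function; requires the
#' original matrix since the fit object does not retain counts.
#'
#' @param object A [fit_count_models()] result.
#' @param m The [umi_counts()] object the fit was computed on.
#' @param model Model name; default the best by BIC.
#' @param ... Unused.
#' @return A genes-by-cells matrix of Pearson residuals.
#' @export
residuals.distfit <- function(object, m, model = NULL, ...) {
  stopifnot(inherits(m, "umi_counts"), all(dim(m$counts) == object$dim))
  model <- canonical_model(if (is.null(model)) best_model(object) else model)
  fit <- object$fits[[model]]
  if (is.null(fit)) stop("model '", model, "' was not fitted")
  mu <- fitted_mu(object, model)
  v <- switch(model,
    poisson = mu,
    binomial = mu * (1 - outer(fit$pi, rep(1, length(object$libsizes)))),
    nb_global = mu + mu^2 / fit$phi_global,
    nb_genewise = mu + mu^2 / fit$phi_gene)
  (as.matrix(m$counts) - mu) / sqrt(pmax(v, .Machine$double.eps))
}

#' Simulate counts from a fitted model
#'
#' Parametric draws at the fitted abundances and the observed library sizes;
#' useful for posterior-predictive style checks.
#'
#' @param object A [fit_count_models()] result.
#' @param nsim Number of replicate matrices.
#' @param seed Integer seed or `NULL`.
#' @param model Model name; default the best by BIC.
#' @param ... Unused.
#' @return A list of `nsim` [umi_counts()] objects.
#' @export
simulate.distfit <- function(object, nsim = 1, seed = NULL, model = NULL, ...) {
  model <- canonical_model(if (is.null(model)) best_model(object) else model)
  fit <- object$fits[[model]]
  if (is.null(fit)) stop("model '", model, "' was not fitted")
  if (!is.null(seed)) set.seed(seed)
  G <- object$dim[1]; C <- object$dim[2]
  mu <- fitted_mu(object, model)
  s <- object$libsizes
  draw <- function() {
    x <- switch(model,
      poisson = matrix(stats::rpois(G * C, as.vector(mu)), G),
      binomial = vapply(seq_len(C), function(c)
        stats::rmultinom(1, round(s[c]), fit$pi)[, 1], integer(G)),
      nb_global = matrix(stats::rnbinom(G * C, size = fit$phi_global,
                                        mu = as.vector(mu)), G),
      nb_genewise = matrix(stats::rnbinom(G * C, size = fit$phi_gene,
                                          mu = as.vector(mu)), G))
    umi_counts(matrix(x, nrow = G), gene_ids = names(fit$pi),
               barcodes = names(s))
  }
  replicate(nsim, draw(), simplify = FALSE)
}

#' Diagnostic panels for a count-distribution comparison
#'
#' Four panels: (1) log10 empirical mean vs log10 empirical variance per
#' gene with the theoretical variance curves of each fitted model; (2) log10
#' empirical mean vs observed zero fraction with the expected zero-fraction
#' curves; (3) BIC per model; (4) quantile-quantile plot of the per-gene
#' Pearson statistics under Poisson against chi-squared quantiles.
#'
#' @param x A [fit_count_models()] result.
#' @param which Subset of `1:4`.
#' @param ... Passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.distfit <- function(x, which = 1:4, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  gs <- x$summaries
  s_bar <- mean(x$libsizes)
  phi <- x$fits$nb_global$phi_global
  pos <- gs$mean > 0
  mu_grid <- 10^seq(log10(min(gs$mean[pos])), log10(max(gs$mean)),
                    length.out = 200)

  if (1 %in% which) {
    graphics::plot(log10(gs$mean[pos]), log10(pmax(gs$variance[pos], 1e-8)),
                   pch = 16, cex = 0.4, col = "grey40",
                   xlab = "log10 empirical mean",
                   ylab = "log10 empirical variance",
                   main = "Mean-variance", ...)
    graphics::lines(log10(mu_grid), log10(mu_grid), col = "blue")
    graphics::lines(log10(mu_grid),
                    log10(pmax(expected_variance("binomial", mu_grid,
                                                 mean_libsize = s_bar), 1e-12)),
                    col = "darkgreen", lty = 2)
    if (!is.null(phi))
      graphics::lines(log10(mu_grid),
                      log10(expected_variance("nb", mu_grid, phi = phi)),
                      col = "red")
    graphics::legend("topleft", c("Poisson", "Binomial", "NB"), bty = "n",
                     col = c("blue", "darkgreen", "red"), lty = c(1, 2, 1))
  }
  if (2 %in% which) {
    graphics::plot(log10(gs$mean[pos]), gs$zero_fraction[pos], pch = 16,
                   cex = 0.4, col = "grey40", ylim = c(0, 1),
                   xlab = "log10 empirical mean",
                   ylab = "observed zero fraction", main = "Zero fractions",
                   ...)
    pi_grid <- mu_grid / s_bar
    graphics::lines(log10(mu_grid),
                    expected_zero_fraction("poisson", pi_grid, x$libsizes),
                    col = "blue")
    graphics::lines(log10(mu_grid),
                    expected_zero_fraction("binomial", pmin(pi_grid, 1),
                                           x$libsizes),
                    col = "darkgreen", lty = 2)
    if (!is.null(phi))
      graphics::lines(log10(mu_grid),
                      expected_zero_fraction("nb", pi_grid, x$libsizes,
                                             phi = phi), col = "red")
  }
  if (3 %in% which) {
    graphics::barplot(x$bic$bic - min(x$bic$bic), names.arg = x$bic$model,
                      ylab = "BIC - min(BIC)", main = "Model comparison",
                      las = 2, ...)
  }
  if (4 %in% which && !is.null(x$gof)) {
    graphics::plot(x$gof$qq$theoretical, x$gof$qq$observed, pch = 16,
                   cex = 0.4, xlab = "chi-squared quantile",
                   ylab = "observed Pearson statistic",
                   main = sprintf("Poisson GOF (df = %d)", x$gof$dof), ...)
    graphics::abline(0, 1, col = "red")
  }
  invisible(x)
}
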