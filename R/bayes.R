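## R-side interface to the weighted BayesB / BayesC Gibbs samplers.

#' MCMC configuration for the marker models
#'
#' Defaults are the analysis-scale settings the package targets: a 110,000
#' iteration chain with the first 10,000 discarded as burn-in and a thinning
#' interval of five; \eqn{\pi} = 0.99 for medium-density panels (use 0.999
#' for high-density). Priors are scaled inverse chi-square with 4 degrees of
#' freedom for both the marker-effect and residual variances.
#'
#' @param n_iter total chain length.
#' @param burnin discarded initial iterations.
#' @param thin thinning interval for saved samples.
#' @param pi prior fraction of markers excluded from the model (held fixed).
#' @param nu_u,nu_e prior degrees of freedom for marker-effect and residual
#'   variances.
#' @param target_genvar prior mean total genetic variance; \code{NULL} =
#'   half the weighted response variance. Determines the marker-effect prior
#'   scale \code{S2u = target*(nu_u-2)/nu_u / ((1-pi)*sum(Var(Z_j)))}.
#' @param seed RNG seed for the chain.
#' @return list of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iter = 110000L, burnin = 10000L, thin = 5L,
                        pi = 0.99, nu_u = 4, nu_e = 4,
                        target_genvar = NULL, seed = 1L) {
  stopifnot(burnin < n_iter, thin >= 1, pi >= 0, pi < 1)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), pi = pi, nu_u = nu_u, nu_e = nu_e,
                 target_genvar = target_genvar, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Fit a weighted BayesB or BayesC marker model
#'
#' Single-site Gibbs sampling of \code{y_i = mu + sum_j Z_ij u_j delta_j +
#' e_i} with heteroscedastic residuals \code{Var(e_i) = sigma2_e / w_i}.
#' BayesC uses one common effect variance for included markers; BayesB a
#' locus-specific variance (drawn from its prior when the locus is currently
#' excluded). \eqn{\pi} is held fixed. Saved samples start after burn-in at
#' the thinning interval.
#'
#' @param Z analysis-coded marker matrix (animals x SNPs, -10/0/10 scale,
#'   typically centred), either a plain matrix or an analysis-coded
#'   [genotype_panel()].
#' @param y response vector (deregressed breeding values).
#' @param weights per-record weights (default 1).
#' @param method \code{"BayesB"} or \code{"BayesC"}.
#' @param config an [mcmc_config()].
#' @param store_samples keep the thinned marker-effect samples (needed for
#'   window variance decomposition).
#' @return object of class \code{bayes_fit}: per-SNP posterior mean effects
#'   and model frequencies, per-sample genetic variance, posterior means of
#'   mu and the variances, the map (if a panel was given), and optionally the
#'   saved effect samples.
#' @export
bayes_fit <- function(Z, y, weights = NULL, method = c("BayesB", "BayesC"),
                      config = mcmc_config(), store_samples = FALSE) {
  method <- match.arg(method)
  map <- NULL
  if (inherits(Z, "genotype_panel")) {
    if (Z$coding != "analysis")
      stop_ibwgp("panel must be in analysis coding; run recode_analysis()")
    map <- Z$map
    Z <- Z$geno
  }
  Z <- as.matrix(Z)
  n <- nrow(Z); k <- ncol(Z)
  if (length(y) != n) stop_ibwgp("length(y) != nrow(Z)")
  if (!all(is.finite(y))) stop_ibwgp("non-finite response")
  if (anyNA(Z)) stop_ibwgp("missing marker codes")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  if (config$pi >= 1) warning("pi = 1: intercept-only model")

  vy <- stats::weighted.mean((y - stats::weighted.mean(y, weights))^2, weights)
  target <- config$target_genvar %||% (0.5 * vy)
  sumvar <- sum(apply(Z, 2L, stats::var))
  S2u <- if (sumvar > 0)
    target * (config$nu_u - 2) / config$nu_u / ((1 - config$pi) * sumvar)
  else 1e-8
  S2e <- (0.5 * vy) * (config$nu_e - 2) / config$nu_e

  set.seed(config$seed)
  res <- cpp_bayes_mcmc(Z, as.numeric(y), as.numeric(weights),
                        method == "BayesB", config$pi, config$n_iter,
                        config$burnin, config$thin, config$nu_u, config$nu_e,
                        S2u, S2e, store_samples)
  fit <- list(method = method, config = config, map = map,
              snp = colnames(Z),
              post_mean_effect = stats::setNames(res$post_mean_effect,
                                                 colnames(Z)),
              model_freq = stats::setNames(res$model_freq, colnames(Z)),
              genvar_samples = res$genvar_samples,
              sigma2e_samples = res$sigma2e_samples,
              sigma2u_samples = res$sigma2u_samples,
              mu_samples = res$mu_samples,
              n_included_samples = res$n_included_samples,
              n_saved = res$n_saved,
              S2u = S2u, S2e = S2e, n = n, k = k,
              effect_samples = if (store_samples) res$effect_samples)
  class(fit) <- "bayes_fit"
  fit
}

#' @exportS3Method print bayes_fit
print.bayes_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit: %d animals x %d SNPs, pi = %g, %d saved samples\n",
    x$method, x$n, x$k, x$config$pi, x$n_saved))
  cat(sprintf("posterior means: mu = %.4f, sigma2_e = %.5f, genetic var = %.5f\n",
              mean(x$mu_samples), mean(x$sigma2e_samples),
              mean(x$genvar_samples)))
  invisible(x)
}

#' @exportS3Method coef bayes_fit
coef.bayes_fit <- function(object, ...) object$post_mean_effect

#' Direct genomic values
#'
#' \eqn{DGV_i = \sum_j Z_{ij} \hat u_j} with \eqn{\hat u} the posterior mean
#' marker effects. \code{Z} must be coded (and centred) identically to the
#' training matrix.
#'
#' @param fit a [bayes_fit()].
#' @param Z analysis-coded marker matrix or panel for the target animals.
#' @return named numeric vector of DGVs.
#' @export
dgv <- function(fit, Z) {
  if (inherits(Z, "genotype_panel")) Z <- Z$geno
  if (ncol(Z) != fit$k ||
      (!is.null(colnames(Z)) && !identical(colnames(Z), fit$snp)))
    stop_ibwgp("SNP set of Z does not match the fitted model")
  drop(Z %*% fit$post_mean_effect)
}

#' @rdname dgv
#' @param object a [bayes_fit()].
#' @param newdata marker matrix/panel (default: refuse, DGVs need genotypes).
#' @param ... unused.
#' @exportS3Method predict bayes_fit
predict.bayes_fit <- function(object, newdata, ...) dgv(object, newdata)

#' Posterior model frequency per SNP
#'
#' Fraction of saved samples in which each marker is in the model.
#' @param fit a [bayes_fit()].
#' @return named numeric vector in [0, 1].
#' @export
model_frequency <- function(fit) fit$model_freq

#' Geweke-style split-chain stationarity z-score
#'
#' Compares the means of the first \code{frac1} and last \code{frac2} of a
#' saved-sample vector, with variances estimated by batch means.
#' @param x numeric vector of saved samples.
#' @param frac1,frac2 fractions of the chain compared.
#' @return z statistic.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[seq.int(n - floor(frac2 * n) + 1L, n)]
  bm <- function(v) {
    nb <- max(2L, floor(sqrt(length(v))))
    m <- floor(length(v) / nb)
    mb <- colMeans(matrix(v[seq_len(nb * m)], m, nb))
    stats::var(mb) / nb
  }
  (mean(a) - mean(b)) / sqrt(bm(a) + bm(b))
}
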