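#' Fit latent Dirichlet process regression by Gibbs sampling
#'
#' Blocked Gibbs sampler for the truncated stick-breaking representation of
#' the model. Each sweep updates, in fixed order: per-SNP component
#' assignments and effect sizes (single-site, with an in-place residual
#' cache), component variances, stick proportions and mixture weights, the
#' concentration parameter, the residual variance, the covariate
#' coefficients, and records the per-sweep PVE
#' \eqn{var(X\beta) / (var(X\beta) + \sigma^2_e)}.
#'
#' @param y numeric phenotype vector.
#' @param X n x p genotype dosage matrix without missing values.
#' @param W covariate matrix including an intercept column; `NULL` for
#'   intercept only.
#' @param K truncation level of the mixture.
#' @param prior a [dpr_prior()]; its `K` is overridden by the `K` argument.
#' @param n_iter total Gibbs sweeps (the reference protocol uses 50,000;
#'   small panels mix with far fewer).
#' @param burn_in discarded sweeps; default 20% of `n_iter`.
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param seed integer seed; the chain is fully reproducible given the seed.
#' @param center center genotype columns to mean zero before fitting
#'   (training means are stored for prediction on new data).
#' @param fix optional list pinning parameters for validation runs: any of
#'   `sigma2k` (length-K vector), `sigma2e` (scalar), `pi` (length-K
#'   weights; also freezes the sticks and concentration), `alpha`
#'   (covariate coefficients).
#' @param keep_gamma,keep_beta store per-kept-sweep assignment / effect
#'   draws (memory O(kept x p); intended for small panels).
#' @param debug recompute the residual from scratch at every sweep and stop
#'   if the cache has drifted beyond 1e-8.
#' @return An object of class `c("dpr_mcmc_fit", "dpr_fit")` with posterior
#'   means (`beta_mean`, `alpha_mean`), `pip`, a `pve` summary, chain traces
#'   in `draws`, and the training column means in `x_center`.
#' @seealso [dpr_vb()] for the variational backend, [predict.dpr_fit()].
#' @export
dpr_mcmc <- function(y, X, W = NULL, K = 4, prior = dpr_prior(K = K),
                     n_iter = 50000, burn_in = floor(0.2 * n_iter),
                     thin = 10, seed = 1, center = TRUE, fix = list(),
                     keep_gamma = FALSE, keep_beta = FALSE, debug = FALSE) {
  dat <- regression_data(y, X, W)
  K <- as.integer(K)
  stopifnot(K >= 1)
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if ((n_iter - burn_in) %/% thin < 1) stop("no sweeps would be kept")

  x_center <- NULL
  Xc <- dat$X
  if (center) {
    x_center <- colMeans(Xc)
    Xc <- sweep(Xc, 2, x_center)
  }

  fix_sigma2k <- !is.null(fix$sigma2k)
  fix_sigma2e <- !is.null(fix$sigma2e)
  fix_pi <- !is.null(fix$pi)
  fix_alpha <- !is.null(fix$alpha)
  sigma2k0 <- if (fix_sigma2k) as.numeric(fix$sigma2k) else rep(1, K)
  if (fix_sigma2k && length(sigma2k0) != K)
    stop("fix$sigma2k must have length K")
  pi0 <- if (fix_pi) as.numeric(fix$pi) else rep(1 / K, K)
  if (fix_pi && (length(pi0) != K || abs(sum(pi0) - 1) > 1e-8))
    stop("fix$pi must be a length-K probability vector")
  alpha0 <- if (fix_alpha) as.numeric(fix$alpha) else rep(0, dat$c)
  if (fix_alpha && length(alpha0) != dat$c)
    stop("fix$alpha must have length ncol(W)")

  set.seed(seed)
  res <- .dpr_gibbs_cpp(dat$y, Xc, dat$W, K,
                        prior$a_sigma, prior$b_sigma,
                        prior$a_lambda, prior$b_lambda,
                        prior$a_e, prior$b_e,
                        n_iter, burn_in, thin,
                        fix_sigma2k, sigma2k0,
                        fix_sigma2e, if (fix_sigma2e) fix$sigma2e else 1,
                        fix_pi, pi0,
                        fix_alpha, alpha0,
                        keep_gamma, keep_beta, debug)

  pve <- pve_from_draws(res$pve_draws)
  draws <- list(sigma2e = as.numeric(res$sigma2e_draws),
                lambda = as.numeric(res$lambda_draws),
                pve = as.numeric(res$pve_draws),
                log_posterior = as.numeric(res$log_posterior_trace),
                pi = res$pi_draws,
                sigma2k = res$sigma2k_draws,
                gamma_counts = res$gamma_counts)
  if (keep_gamma) draws$gamma <- res$gamma_draws
  if (keep_beta) draws$beta <- res$beta_draws

  structure(list(
    backend = "mcmc",
    beta_mean = as.numeric(res$beta_mean),
    alpha_mean = as.numeric(res$alpha_mean),
    pip = as.numeric(res$pip),
    pve = pve,
    draws = draws,
    n_kept = res$n_kept,
    K = K, prior = prior,
    config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                  seed = seed, center = center, fix = fix),
    x_center = x_center,
    n = dat$n, p = dat$p
  ), class = c("dpr_mcmc_fit", "dpr_fit"))
}

#' @export
print.dpr_fit <- function(x, ...) {
  cat(sprintf("Dirichlet process regression fit (%s backend)\n",
              toupper(x$backend)))
  cat(sprintf("  n = %d individuals, p = %d SNPs, K = %d components\n",
              x$n, x$p, x$K))
  cat(sprintf("  PVE estimate: %.3f", x$pve$mean))
  if (!is.null(x$pve$sd) && is.finite(x$pve$sd))
    cat(sprintf(" (sd %.3f, 95%% interval %.3f-%.3f)",
                x$pve$sd, x$pve$interval[1], x$pve$interval[2]))
  cat("\n")
  invisible(x)
}

#' Write chain traces to a tab-delimited file
#'
#' @param fit a `dpr_mcmc_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "dpr_mcmc_fit"))
  tr <- data.frame(iteration = seq_len(fit$n_kept),
                   sigma2e = fit$draws$sigma2e,
                   lambda = fit$draws$lambda,
                   pve = fit$draws$pve,
                   log_posterior = fit$draws$log_posterior)
  write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
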