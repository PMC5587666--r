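#' Predict phenotypes from a fitted model
#'
#' Plug-in prediction \eqn{\hat y = W \hat\alpha + X \hat\beta} using the
#' posterior-mean coefficients. New genotypes are centered with the
#' training-column means stored in the fit.
#'
#' @param object a `dpr_fit` from [dpr_mcmc()] or [dpr_vb()].
#' @param X_new genotype dosage matrix for the new individuals (raw scale).
#' @param W_new covariate matrix; `NULL` for intercept only.
#' @param ... unused.
#' @return Numeric vector of predicted phenotypes.
#' @export
predict.dpr_fit <- function(object, X_new, W_new = NULL, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != object$p)
    stop("X_new must have ", object$p, " columns")
  if (is.null(W_new)) W_new <- matrix(1, nrow(X_new), 1)
  W_new <- as.matrix(W_new)
  if (ncol(W_new) != length(object$alpha_mean))
    stop("W_new must have ", length(object$alpha_mean), " columns")
  if (!is.null(object$x_center)) X_new <- sweep(X_new, 2, object$x_center)
  as.numeric(W_new %*% object$alpha_mean + X_new %*% object$beta_mean)
}

#' Squared correlation coefficient
#'
#' Squared Pearson correlation between observed and predicted values.
#' A degenerate (zero-variance) prediction scores 0 and carries a
#' `degenerate` attribute rather than returning `NA`.
#'
#' @param y,yhat numeric vectors of equal length (>= 2).
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  if (sd(y) == 0) stop("y has zero variance")
  if (sd(yhat) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cor(y, yhat)^2
}

#' Mean squared error
#'
#' @inheritParams r_squared
#' @return Nonnegative scalar.
#' @export
mse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  mean((y - yhat)^2)
}

#' Monte Carlo cross-validation
#'
#' Repeated random train/test splitting. Per split the method is fitted on
#' the training fold only: genotype centering means and (optionally) the
#' phenotype quantile-normalization map are learned on the training fold
#' and applied to the test fold, so no test information leaks into
#' training.
#'
#' @param y phenotype vector.
#' @param X genotype dosage matrix (raw scale, no missing values).
#' @param method fitting backend: function `f(y_train, X_train, X_test)`
#'   returning test-set predictions.
#' @param n_splits number of random splits.
#' @param train_frac fraction of individuals in each training fold.
#' @param seed integer seed; splits and scores are reproducible.
#' @param quantile_norm quantile-normalize the training phenotype to a
#'   standard normal and map the test phenotype through the training fold's
#'   empirical quantiles.
#' @return An object of class `cv_report`: list with `results` (data frame
#'   `split`, `r2`, `mse`), `summary` (means and standard deviations),
#'   `splits` (list of test-index vectors).
#' @export
monte_carlo_cv <- function(y, X, method, n_splits = 20, train_frac = 0.8,
                           seed = 1, quantile_norm = FALSE) {
  y <- as.numeric(y); X <- as.matrix(X)
  n <- length(y)
  if (n < 10) stop("need at least 10 individuals")
  n_train <- floor(train_frac * n)
  if (n_train < 2 || n_train >= n) stop("train_frac leaves an empty split")
  set.seed(seed)
  splits <- lapply(seq_len(n_splits), function(s) sort(sample.int(n, n_train)))

  res <- lapply(seq_len(n_splits), function(s) {
    train <- splits[[s]]
    test <- setdiff(seq_len(n), train)
    y_tr <- y[train]; y_te <- y[test]
    if (quantile_norm) {
      qn_tr <- quantile_normalize(y_tr)
      # map test values through the training fold's rank-to-quantile curve
      o <- order(y_tr)
      y_te <- approx(y_tr[o], qn_tr[o], xout = y_te, rule = 2, ties = "ordered")$y
      y_tr <- qn_tr
    }
    ctr <- center_genotypes(X[train, , drop = FALSE])
    Xte <- center_genotypes(X[test, , drop = FALSE], means = ctr$means)$X
    yhat <- method(y_tr, ctr$X, Xte)
    data.frame(split = s, r2 = as.numeric(r_squared(y_te, yhat)),
               mse = mse(y_te, yhat))
  })
  results <- do.call(rbind, res)
  structure(list(
    results = results,
    summary = data.frame(r2_mean = mean(results$r2), r2_sd = sd(results$r2),
                         mse_mean = mean(results$mse), mse_sd = sd(results$mse)),
    splits = lapply(splits, function(tr) setdiff(seq_len(n), tr)),
    train_indices = splits,
    n_splits = n_splits, train_frac = train_frac, seed = seed
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Monte Carlo cross-validation: %d splits at %.0f%%/%.0f%%\n",
              x$n_splits, 100 * x$train_frac, 100 * (1 - x$train_frac)))
  cat(sprintf("  R2  %.4f (sd %.4f)\n", x$summary$r2_mean, x$summary$r2_sd))
  cat(sprintf("  MSE %.4f (sd %.4f)\n", x$summary$mse_mean, x$summary$mse_sd))
  invisible(x)
}

#' Posterior summary of the proportion of variance explained
#'
#' Mean, standard deviation and central 95% interval of the per-draw PVE
#' (SNP heritability) trace \eqn{var(X\beta) / (var(X\beta) + \sigma^2_e)}.
#'
#' @param draws numeric vector of per-draw PVE values.
#' @return List with `mean`, `sd`, `interval`.
#' @export
pve_from_draws <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) == 0) stop("empty PVE trace")
  list(mean = mean(draws), sd = sd(draws),
       interval = unname(quantile(draws, c(0.025, 0.975))))
}

#' Posterior inclusion probabilities from assignment draws
#'
#' The PIP of a SNP is the fraction of kept draws in which it is assigned
#' to any mixture component other than the smallest-variance ("background")
#' component, identified per draw.
#'
#' @param gamma_draws kept x p integer matrix of component assignments
#'   (from [dpr_mcmc()] with `keep_gamma = TRUE`).
#' @param sigma2k_draws kept x K matrix of component-variance draws.
#' @return Numeric vector of per-SNP PIPs. With K = 1 all PIPs are 0 (with
#'   a warning): there is no non-background component.
#' @export
pip_from_draws <- function(gamma_draws, sigma2k_draws) {
  gamma_draws <- as.matrix(gamma_draws)
  sigma2k_draws <- as.matrix(sigma2k_draws)
  stopifnot(nrow(gamma_draws) == nrow(sigma2k_draws))
  if (ncol(sigma2k_draws) == 1) {
    warning("K = 1: no non-background component, all PIPs are 0")
    return(rep(0, ncol(gamma_draws)))
  }
  kmin <- max.col(-sigma2k_draws, ties.method = "first")
  colMeans(gamma_draws != kmin)
}

#' Genetic relatedness matrix
#'
#' \eqn{GRM = X_s X_s^T / p} from column-standardized genotypes (mean 0,
#' variance 1).
#'
#' @param X genotype matrix (n x p, p >= 2), raw or standardized.
#' @param standardize standardize columns before computing the GRM.
#' @return n x n relatedness matrix.
#' @export
compute_grm <- function(X, standardize = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two SNPs")
  if (standardize) {
    sds <- apply(X, 2, sd)
    keep <- sds > 0
    X <- scale(X[, keep, drop = FALSE])
  }
  tcrossprod(X) / ncol(X)
}

#' Effective number of chromosome segments
#'
#' \eqn{M_e = 1 / var(\text{off-diagonal GRM entries})}: small values
#' indicate related individuals, large values unrelated ones.
#'
#' @param grm a square relatedness matrix from [compute_grm()].
#' @return Scalar M_e.
#' @export
effective_segments <- function(grm) {
  grm <- as.matrix(grm)
  if (nrow(grm) != ncol(grm)) stop("grm must be square")
  off <- grm[lower.tri(grm)]
  if (length(off) < 2) stop("need at least 3 individuals")
  1 / var(off)
}
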