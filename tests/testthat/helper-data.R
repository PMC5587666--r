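# Shared fixture builders; everything is generated in code at test time.

# small dense regression problem with known ridge structure
make_ridge_problem <- function(n = 20, p = 3, seed = 10, beta = NULL,
                               sd_e = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- rnorm(p, 0, 0.7)
  y <- as.numeric(X %*% beta + rnorm(n, 0, sd_e))
  list(y = y, X = X, beta = beta)
}

# closed-form Gaussian posterior mean for K = 1 with fixed variances,
# on centered genotypes (centering makes beta and the intercept independent)
ridge_posterior_mean <- function(y, X, sigma2, sigma2e) {
  Xc <- scale(X, scale = FALSE)
  p <- ncol(Xc)
  as.numeric(solve(crossprod(Xc) / sigma2e + diag(p) / sigma2,
                   crossprod(Xc, y) / sigma2e))
}

# genotype panel with planted QC failures:
#   snp1 clean; snp2 HWE failure (all het); snp3 low call rate;
#   snp4 rare (MAF < 1%); snp5 fully common but with one missing call
make_qc_panel <- function(n = 200) {
  D <- cbind(
    snp1 = rbinom(n, 2, 0.3),
    snp2 = rep(1, n),
    snp3 = c(rep(NA_real_, ceiling(0.1 * n)),
             rbinom(n - ceiling(0.1 * n), 2, 0.4)),
    snp4 = c(1, rep(0, n - 1)),
    snp5 = c(NA_real_, rbinom(n - 1, 2, 0.45))
  )
  genotype_matrix(D)
}

# batch-means Monte Carlo standard error of a chain's mean
mcse_batch <- function(v, n_batches = 25) {
  m <- n_batches * (length(v) %/% n_batches)
  bm <- colMeans(matrix(v[seq_len(m)], ncol = n_batches))
  sd(bm) / sqrt(n_batches)
}
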