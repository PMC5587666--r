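#' Fit latent Dirichlet process regression by variational Bayes
#'
#' Mean-field coordinate-ascent variational inference for the truncated
#' stick-breaking model, with the factorization
#' \deqn{q = \prod_i q(\beta_i, \gamma_i) \prod_k q(\nu_k) q(\sigma^2_k)
#'       \cdot q(\sigma^2_e)\, q(\lambda)\, q(\alpha),}
#' where each per-SNP factor is structured as
#' \eqn{q(\gamma_i) q(\beta_i | \gamma_i)} with
#' \eqn{q(\beta_i | \gamma_i = k) = N(m_{ik}, s^2_{ik})}. All coordinate
#' updates are exact conjugate maximizations, so the evidence lower bound
#' (ELBO) is non-decreasing across iterations. Initialization is
#' deterministic (uniform responsibilities, zero means, prior variance
#' factors, OLS covariate fit), so the converged state depends only on the
#' data.
#'
#' @inheritParams dpr_mcmc
#' @param tol relative ELBO change below which iteration stops.
#' @param max_iter maximum number of coordinate-ascent cycles.
#' @param seed accepted for interface parity with [dpr_mcmc()]; the default
#'   deterministic initialization ignores it.
#' @return An object of class `c("dpr_vb_fit", "dpr_fit")` with posterior
#'   summaries (`beta_mean`, `alpha_mean`, `pip`, `pve`), the variational
#'   factors (`phi`, `m`, `s2`, `stick_params`, `var_params`,
#'   `resid_params`, `conc_params`, `alpha_mean`, `alpha_cov`), the
#'   `elbo_trace`, and a `converged` flag. Non-convergence raises a warning
#'   and returns partial results.
#' @export
dpr_vb <- function(y, X, W = NULL, K = 4, prior = dpr_prior(K = K),
                   tol = 1e-5, max_iter = 1000, seed = 1,
                   center = TRUE, fix = list()) {
  dat <- regression_data(y, X, W)
  K <- as.integer(K)
  stopifnot(K >= 1)

  x_center <- NULL
  Xc <- dat$X
  if (center) {
    x_center <- colMeans(Xc)
    Xc <- sweep(Xc, 2, x_center)
  }
  st <- .vb_init(dat$y, Xc, dat$W, K, prior, fix)

  elbo_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- .vb_cycle(st)
    elbo_trace[it] <- .vb_elbo(st)
    if (it > 1) {
      rel <- abs(elbo_trace[it] - elbo_trace[it - 1]) /
        (abs(elbo_trace[it - 1]) + .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("variational inference did not converge in ", max_iter,
            " iterations; returning partial results")

  beta_mean <- rowSums(st$phi * st$m)
  g_val <- as.numeric(Xc %*% beta_mean)
  Es2e <- if (st$fix_sigma2e) st$sigma2e_fix else st$be / (st$ae - 1)
  vg <- var(g_val)
  pve <- list(mean = vg / (vg + Es2e), sd = NA_real_,
              interval = c(NA_real_, NA_real_))

  s2k_mean <- .vb_sigma2k_mean(st)
  if (K == 1) {
    pip <- rep(0, dat$p)
  } else {
    kmin <- which.min(s2k_mean)
    pip <- 1 - st$phi[, kmin]
  }

  structure(list(
    backend = "vb",
    beta_mean = beta_mean,
    alpha_mean = as.numeric(st$mu_a),
    pip = pip,
    pve = pve,
    phi = st$phi, m = st$m, s2 = st$s2,
    stick_params = if (K > 1) cbind(shape1 = st$kap1, shape2 = st$kap2),
    var_params = if (!st$fix_sigma2k) cbind(shape = st$av, rate = st$bv),
    resid_params = if (!st$fix_sigma2e) c(shape = st$ae, rate = st$be),
    conc_params = c(shape = st$al, rate = st$bl),
    alpha_cov = st$alpha_cov,
    sigma2k_mean = s2k_mean,
    sigma2e_mean = Es2e,
    elbo_trace = elbo_trace,
    converged = converged,
    K = K, prior = prior,
    config = list(tol = tol, max_iter = max_iter, seed = seed,
                  center = center, fix = fix),
    x_center = x_center,
    n = dat$n, p = dat$p
  ), class = c("dpr_vb_fit", "dpr_fit"))
}

.vb_sigma2k_mean <- function(st) {
  if (st$fix_sigma2k) st$sigma2k_fix
  else st$bv / pmax(st$av - 1, 1e-8)
}

.vb_init <- function(y, X, W, K, prior, fix) {
  n <- length(y); p <- ncol(X); c <- ncol(W)
  fix_sigma2k <- !is.null(fix$sigma2k)
  fix_sigma2e <- !is.null(fix$sigma2e)
  fix_alpha <- !is.null(fix$alpha)
  fix_pi <- !is.null(fix$pi)
  if (fix_sigma2k && length(fix$sigma2k) != K)
    stop("fix$sigma2k must have length K")
  if (fix_pi && (length(fix$pi) != K || abs(sum(fix$pi) - 1) > 1e-8))
    stop("fix$pi must be a length-K probability vector")

  WtW <- crossprod(W)
  WtWinv <- tryCatch(solve(WtW), error = function(e)
    stop("collinear covariates: W'W is singular"))
  mu_a <- if (fix_alpha) as.numeric(fix$alpha)
          else as.numeric(WtWinv %*% crossprod(W, y))
  r0 <- y - as.numeric(W %*% mu_a)

  st <- list(
    y = y, X = X, W = W, n = n, p = p, c = c, K = K, prior = prior,
    xtx = colSums(X^2), WtW = WtW, WtWinv = WtWinv,
    ldet_WtW = as.numeric(determinant(WtW, logarithm = TRUE)$modulus),
    fix_sigma2k = fix_sigma2k, sigma2k_fix = fix$sigma2k,
    fix_sigma2e = fix_sigma2e, sigma2e_fix = fix$sigma2e,
    fix_alpha = fix_alpha, fix_pi = fix_pi, pi_fix = fix$pi,
    phi = matrix(1 / K, p, K), m = matrix(0, p, K), s2 = matrix(1, p, K),
    kap1 = if (K > 1) rep(1, K - 1), kap2 = if (K > 1) rep(1, K - 1),
    av = rep(prior$a_sigma, K), bv = rep(prior$b_sigma, K),
    ae = prior$a_e + n / 2,
    be = prior$b_e + sum(r0^2) / 2,
    al = prior$a_lambda, bl = prior$b_lambda,
    mu_a = mu_a, alpha_cov = NULL, eiv_e_alpha = NA_real_,
    rbar = r0  # expected residual: y - W E[alpha] - X E[beta]
  )
  if (!fix_alpha) {
    eiv <- st$ae / st$be
    st$alpha_cov <- WtWinv / eiv
    st$eiv_e_alpha <- eiv
  }
  st
}

.vb_expectations <- function(st) {
  K <- st$K
  eiv_k <- if (st$fix_sigma2k) 1 / st$sigma2k_fix else st$av / st$bv
  elog_k <- if (st$fix_sigma2k) log(st$sigma2k_fix)
            else log(st$bv) - digamma(st$av)
  eiv_e <- if (st$fix_sigma2e) 1 / st$sigma2e_fix else st$ae / st$be
  elog_e <- if (st$fix_sigma2e) log(st$sigma2e_fix)
            else log(st$be) - digamma(st$ae)
  if (st$fix_pi) {
    elogpi <- log(st$pi_fix)
    elognu <- elog1mnu <- NULL
  } else if (K > 1) {
    dg <- digamma(st$kap1 + st$kap2)
    elognu <- digamma(st$kap1) - dg
    elog1mnu <- digamma(st$kap2) - dg
    elogpi <- c(elognu, 0) + c(0, cumsum(elog1mnu))
  } else {
    elogpi <- 0
    elognu <- elog1mnu <- NULL
  }
  list(eiv_k = eiv_k, elog_k = elog_k, eiv_e = eiv_e, elog_e = elog_e,
       elogpi = elogpi, elognu = elognu, elog1mnu = elog1mnu,
       elam = st$al / st$bl, eloglam = digamma(st$al) - log(st$bl))
}

# One full coordinate-ascent cycle; every block is an exact CAVI update.
.vb_cycle <- function(st) {
  K <- st$K
  ex <- .vb_expectations(st)

  # --- per-SNP structured factors q(beta_i, gamma_i) ---
  eb <- rowSums(st$phi * st$m)
  rbar <- st$rbar
  X <- st$X
  for (i in seq_len(st$p)) {
    xi <- X[, i]
    if (eb[i] != 0) rbar <- rbar + xi * eb[i]
    s2i <- 1 / (st$xtx[i] * ex$eiv_e + ex$eiv_k)
    mi <- s2i * ex$eiv_e * sum(xi * rbar)
    lphi <- ex$elogpi - 0.5 * ex$elog_k + 0.5 * log(s2i) + mi^2 / (2 * s2i)
    lphi <- lphi - max(lphi)
    phii <- exp(lphi); phii <- phii / sum(phii)
    st$phi[i, ] <- phii
    st$m[i, ] <- mi
    st$s2[i, ] <- s2i
    eb[i] <- sum(phii * mi)
    if (eb[i] != 0) rbar <- rbar - xi * eb[i]
  }
  st$rbar <- rbar

  nk <- colSums(st$phi)                       # expected occupancies
  ssk <- colSums(st$phi * (st$m^2 + st$s2))   # expected squared effects

  # --- component variances ---
  if (!st$fix_sigma2k) {
    st$av <- st$prior$a_sigma + nk / 2
    st$bv <- st$prior$b_sigma + ssk / 2
  }

  # --- sticks and concentration ---
  if (!st$fix_pi && K > 1) {
    tail_n <- rev(cumsum(rev(nk)))[-1]
    st$kap1 <- 1 + nk[-K]
    st$kap2 <- ex$elam + tail_n
    dg <- digamma(st$kap1 + st$kap2)
    elog1mnu <- digamma(st$kap2) - dg
    st$al <- st$prior$a_lambda + K - 1
    st$bl <- st$prior$b_lambda - sum(elog1mnu)
  }

  # --- residual variance ---
  er2 <- .vb_expected_rss(st)
  if (!st$fix_sigma2e) {
    st$ae <- st$prior$a_e + st$n / 2
    st$be <- st$prior$b_e + er2 / 2
  }

  # --- covariate coefficients ---
  if (!st$fix_alpha) {
    ex2 <- .vb_expectations(st)
    eb <- rowSums(st$phi * st$m)
    yXb <- st$y - as.numeric(st$X %*% eb)
    st$mu_a <- as.numeric(st$WtWinv %*% crossprod(st$W, yXb))
    st$alpha_cov <- st$WtWinv / ex2$eiv_e
    st$eiv_e_alpha <- ex2$eiv_e
    st$rbar <- yXb - as.numeric(st$W %*% st$mu_a)
  }
  st
}

# E_q || y - W alpha - X beta ||^2 under the current factors
.vb_expected_rss <- function(st) {
  eb <- rowSums(st$phi * st$m)
  eb2 <- rowSums(st$phi * (st$m^2 + st$s2))
  vb <- pmax(eb2 - eb^2, 0)
  rbar <- st$y - as.numeric(st$W %*% st$mu_a) - as.numeric(st$X %*% eb)
  tr_w <- if (st$fix_alpha) 0 else st$c / st$eiv_e_alpha
  sum(rbar^2) + tr_w + sum(st$xtx * vb)
}

# Evidence lower bound for the current factors (flat prior on alpha).
.vb_elbo <- function(st) {
  K <- st$K; pr <- st$prior
  ex <- .vb_expectations(st)
  er2 <- .vb_expected_rss(st)

  elbo <- -0.5 * st$n * log(2 * pi) - 0.5 * st$n * ex$elog_e -
    0.5 * ex$eiv_e * er2

  # E[log p(beta, gamma | nu, sigma2_k)]
  ms <- st$m^2 + st$s2
  elbo <- elbo + sum(st$phi * (
    rep(ex$elogpi, each = st$p) - 0.5 * log(2 * pi) -
      rep(ex$elog_k, each = st$p) / 2 -
      ms * rep(ex$eiv_k, each = st$p) / 2))

  # entropy of the structured per-SNP factors
  lphi <- log(pmax(st$phi, .Machine$double.xmin))
  elbo <- elbo - sum(st$phi * lphi) +
    sum(st$phi * 0.5 * (log(2 * pi * st$s2) + 1))

  if (!st$fix_pi && K > 1) {
    # E[log p(nu | lambda)] + H[q(nu)]
    elbo <- elbo + sum(ex$eloglam + (ex$elam - 1) * ex$elog1mnu)
    elbo <- elbo + sum(lbeta(st$kap1, st$kap2) -
                         (st$kap1 - 1) * digamma(st$kap1) -
                         (st$kap2 - 1) * digamma(st$kap2) +
                         (st$kap1 + st$kap2 - 2) * digamma(st$kap1 + st$kap2))
  }
  if (!st$fix_pi) {
    # E[log p(lambda)] + H[q(lambda)]
    elbo <- elbo + pr$a_lambda * log(pr$b_lambda) - lgamma(pr$a_lambda) +
      (pr$a_lambda - 1) * ex$eloglam - pr$b_lambda * ex$elam
    elbo <- elbo + st$al - log(st$bl) + lgamma(st$al) +
      (1 - st$al) * digamma(st$al)
  }
  if (!st$fix_sigma2k) {
    elbo <- elbo + sum(pr$a_sigma * log(pr$b_sigma) - lgamma(pr$a_sigma) -
                         (pr$a_sigma + 1) * ex$elog_k - pr$b_sigma * ex$eiv_k)
    elbo <- elbo + sum(st$av + log(st$bv) + lgamma(st$av) -
                         (1 + st$av) * digamma(st$av))
  }
  if (!st$fix_sigma2e) {
    elbo <- elbo + pr$a_e * log(pr$b_e) - lgamma(pr$a_e) -
      (pr$a_e + 1) * ex$elog_e - pr$b_e * ex$eiv_e
    elbo <- elbo + st$ae + log(st$be) + lgamma(st$ae) -
      (1 + st$ae) * digamma(st$ae)
  }
  if (!st$fix_alpha) {
    # entropy of q(alpha); flat prior contributes no varying term
    elbo <- elbo + 0.5 * (st$c * log(2 * pi * exp(1)) - st$ldet_WtW -
                            st$c * log(st$eiv_e_alpha))
  }
  elbo
}

#' Evidence lower bound of a variational fit
#'
#' Recomputes the mean-field ELBO from the stored variational factors of a
#' [dpr_vb()] fit and the data it was fitted to; deterministic for a given
#' state. Matches the last entry of `fit$elbo_trace`.
#'
#' @param fit a `dpr_vb_fit`.
#' @param y,X,W the data the model was fitted to (`X` raw, as passed to
#'   [dpr_vb()]; it is re-centered with the stored training means).
#' @return The ELBO value (scalar).
#' @export
compute_elbo <- function(fit, y, X, W = NULL) {
  stopifnot(inherits(fit, "dpr_vb_fit"))
  dat <- regression_data(y, X, W)
  Xc <- dat$X
  if (!is.null(fit$x_center)) Xc <- sweep(Xc, 2, fit$x_center)
  st <- .vb_init(dat$y, Xc, dat$W, fit$K, fit$prior, fit$config$fix)
  st$phi <- fit$phi; st$m <- fit$m; st$s2 <- fit$s2
  if (fit$K > 1 && !st$fix_pi) {
    st$kap1 <- fit$stick_params[, "shape1"]
    st$kap2 <- fit$stick_params[, "shape2"]
  }
  if (!st$fix_sigma2k) {
    st$av <- fit$var_params[, "shape"]; st$bv <- fit$var_params[, "rate"]
  }
  if (!st$fix_sigma2e) {
    st$ae <- fit$resid_params[["shape"]]; st$be <- fit$resid_params[["rate"]]
  }
  st$al <- fit$conc_params[["shape"]]; st$bl <- fit$conc_params[["rate"]]
  st$mu_a <- fit$alpha_mean
  if (!st$fix_alpha) {
    st$alpha_cov <- fit$alpha_cov
    st$eiv_e_alpha <- 1 / (fit$alpha_cov[1, 1] / st$WtWinv[1, 1])
  }
  .vb_elbo(st)
}
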