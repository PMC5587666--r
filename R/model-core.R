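#' Assemble a regression data set
#'
#' Bundles the phenotype vector, covariate matrix and genotype dosage matrix
#' of the model \eqn{y = W\alpha + X\beta + \epsilon} and validates their
#' dimensions. `W` defaults to an intercept-only design; when supplied it
#' must contain an all-ones column.
#'
#' @param y numeric phenotype vector of length n.
#' @param X n x p genotype dosage matrix (no missing values; impute first).
#' @param W n x c covariate matrix including an intercept column of ones, or
#'   `NULL` for intercept only.
#' @return An object of class `regression_data`: a list with elements
#'   `y`, `W`, `X`, `n`, `p`, `c`.
#' @export
regression_data <- function(y, X, W = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (nrow(W) != n) stop("nrow(W) must equal length(y)")
  has_ones <- any(apply(W, 2, function(w) all(w == 1)))
  if (!has_ones) stop("W must contain an all-ones intercept column")
  if (anyNA(X)) stop("X contains missing values; run mean_impute() first")
  if (anyNA(y)) stop("y contains missing values")
  structure(list(y = y, W = W, X = X, n = n, p = ncol(X), c = ncol(W)),
            class = "regression_data")
}

#' Hyper-prior specification for the Dirichlet process regression model
#'
#' The effect-size variances follow a Dirichlet process with inverse-gamma
#' base distribution `InvGamma(a_sigma, b_sigma)` and concentration
#' \eqn{\lambda \sim Gamma(a_lambda, b_lambda)} (shape/rate). The residual
#' variance has an `InvGamma(a_e, b_e)` prior. All base-distribution
#' parameters default to small values so the prior stays weakly informative.
#'
#' @param K truncation level of the stick-breaking representation (>= 1).
#' @param a_sigma,b_sigma shape/rate of the inverse-gamma base distribution.
#' @param a_lambda,b_lambda shape/rate of the gamma prior on the
#'   concentration parameter.
#' @param a_e,b_e shape/rate of the inverse-gamma prior on the residual
#'   variance.
#' @return An object of class `dpr_prior`.
#' @export
dpr_prior <- function(K = 4, a_sigma = 0.1, b_sigma = 0.1,
                      a_lambda = 1, b_lambda = 1,
                      a_e = 0.1, b_e = 0.1) {
  K <- as.integer(K)
  vals <- c(a_sigma = a_sigma, b_sigma = b_sigma, a_lambda = a_lambda,
            b_lambda = b_lambda, a_e = a_e, b_e = b_e)
  if (K < 1L) stop("K must be a positive integer")
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all shape/rate hyper-parameters must be strictly positive")
  structure(list(K = K, a_sigma = a_sigma, b_sigma = b_sigma,
                 a_lambda = a_lambda, b_lambda = b_lambda,
                 a_e = a_e, b_e = b_e),
            class = "dpr_prior")
}

#' Mixture state of the truncated stick-breaking representation
#'
#' @param nu stick proportions in (0, 1], last element must equal 1.
#' @param sigma2 component variances (positive), same length as `nu`.
#' @param lambda_ concentration parameter (positive).
#' @return An object of class `mixture_state` with elements `nu`, `pi`,
#'   `sigma2`, `lambda_`; `pi` is recomputed from `nu`.
#' @export
mixture_state <- function(nu, sigma2, lambda_ = 1) {
  pi <- stick_breaking_weights(nu)
  if (length(sigma2) != length(nu))
    stop("sigma2 and nu must have the same length")
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("all component variances must be strictly positive")
  if (!is.finite(lambda_) || lambda_ <= 0)
    stop("lambda_ must be strictly positive")
  structure(list(nu = as.numeric(nu), pi = pi,
                 sigma2 = as.numeric(sigma2), lambda_ = lambda_),
            class = "mixture_state")
}

#' Stick-breaking weights
#'
#' Converts stick proportions into mixture weights,
#' \eqn{\pi_k = \nu_k \prod_{l<k} (1 - \nu_l)}, under the truncation
#' convention \eqn{\nu_K = 1} which guarantees the weights sum to one.
#'
#' @param nu numeric vector of stick proportions, each in (0, 1], with the
#'   last element equal to 1.
#' @return Numeric vector of mixture weights summing to 1.
#' @examples
#' stick_breaking_weights(c(0.5, 0.5, 1)) # 0.50 0.25 0.25
#' @export
stick_breaking_weights <- function(nu) {
  nu <- as.numeric(nu)
  if (length(nu) < 1L) stop("nu must have length >= 1")
  if (any(!is.finite(nu)) || any(nu <= 0) || any(nu > 1))
    stop("each stick proportion must lie in (0, 1]")
  K <- length(nu)
  if (nu[K] != 1)
    stop("truncation violation: the last stick proportion must equal 1")
  rem <- cumprod(c(1, 1 - nu[-K]))
  nu * rem
}

#' Effect-size mixture density
#'
#' Density of the induced zero-mean normal scale-mixture,
#' \eqn{f(b) = \sum_k \pi_k \phi(b; 0, \sigma^2_k)}.
#'
#' @param b numeric vector of effect-size values.
#' @param state a [mixture_state()].
#' @return Numeric vector of density values, same length as `b`.
#' @export
mixture_density <- function(b, state) {
  stopifnot(inherits(state, "mixture_state"))
  sdev <- sqrt(state$sigma2)
  out <- numeric(length(b))
  for (k in seq_along(state$pi))
    out <- out + state$pi[k] * dnorm(b, 0, sdev[k])
  out
}

#' Draw effect sizes from the truncated Dirichlet process prior
#'
#' Samples \eqn{\lambda} from its gamma hyper-prior (unless fixed), stick
#' proportions \eqn{\nu_k \sim Beta(1, \lambda)} (with \eqn{\nu_K = 1}),
#' component variances from the inverse-gamma base distribution (unless
#' fixed), component assignments from the stick-breaking weights, and
#' effects from the assigned normal components.
#'
#' @param prior a [dpr_prior()].
#' @param p number of effects to draw.
#' @param seed integer seed; draws are reproducible given the seed.
#' @param lambda_ optional fixed concentration (skips the hyper-prior draw).
#' @param sigma2 optional fixed vector of component variances (length K).
#' @return A list with `beta` (length p), `gamma` (assignments in 1..K) and
#'   `state` (the sampled [mixture_state()]).
#' @export
sample_prior_effects <- function(prior, p, seed, lambda_ = NULL, sigma2 = NULL) {
  stopifnot(inherits(prior, "dpr_prior"), p >= 1)
  set.seed(seed)
  K <- prior$K
  if (is.null(lambda_))
    lambda_ <- rgamma(1, shape = prior$a_lambda, rate = prior$b_lambda)
  nu <- if (K > 1) c(rbeta(K - 1, 1, lambda_), 1) else 1
  if (is.null(sigma2))
    sigma2 <- 1 / rgamma(K, shape = prior$a_sigma, rate = prior$b_sigma)
  state <- mixture_state(nu, sigma2, lambda_)
  gam <- sample.int(K, p, replace = TRUE, prob = state$pi)
  beta <- rnorm(p, 0, sqrt(state$sigma2[gam]))
  list(beta = beta, gamma = gam, state = state)
}
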