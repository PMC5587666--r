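#' Simulate an unlinked genotype panel
#'
#' Per SNP, a minor allele frequency is drawn uniformly from `maf_range`
#' and dosages are sampled as Binomial(2, MAF), independently across SNPs
#' and individuals (no linkage disequilibrium, no missingness).
#'
#' @param n number of individuals.
#' @param p number of SNPs.
#' @param maf_range length-2 range for the per-SNP allele frequency.
#' @param seed integer seed.
#' @return A [genotype_matrix()]; the drawn frequencies are stored in the
#'   `maf_true` attribute.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5), seed = 1) {
  stopifnot(n >= 1, p >= 1)
  maf_range <- as.numeric(maf_range)
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 1)
    stop("degenerate maf_range: need 0 < lower <= upper <= 1")
  set.seed(seed)
  maf <- runif(p, maf_range[1], maf_range[2])
  D <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  gm <- genotype_matrix(D)
  attr(gm, "maf_true") <- maf
  gm
}

#' Specification of a phenotype simulation scenario
#'
#' Four genetic architectures:
#' \describe{
#'   \item{I}{all SNPs causal in four effect-size groups of 10, 100, 1000
#'     and the remaining SNPs, explaining shares 0.05/0.15/0.20/0.60 of the
#'     genetic variance.}
#'   \item{II}{sparse: the same three leading groups with shares
#'     0.1/0.2/0.7; the remaining SNPs have exactly zero effect.}
#'   \item{III}{two groups: `c_large` SNPs vs the rest, shares 0.2/0.8.}
#'   \item{IV}{all SNPs causal in one group, with effects drawn from a
#'     normal, t (4 df) or Laplace distribution.}
#' }
#' Raw effects are standard normal in scenarios I-III.
#'
#' @param scenario one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param pve total proportion of phenotypic variance explained, in (0, 1).
#' @param effect_family for scenario IV: `"normal"`, `"t4"` or `"laplace"`.
#' @param c_large for scenario III: size of the large-effect group
#'   (10, 100 or 1000 in the reference design).
#' @param group_sizes,group_var_shares optional overrides of the per-group
#'   SNP counts and genetic-variance shares (needed for panels too small
#'   for the default group sizes).
#' @param seed integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(scenario = c("I", "II", "III", "IV"), pve = 0.5,
                            effect_family = c("normal", "t4", "laplace"),
                            c_large = 10, group_sizes = NULL,
                            group_var_shares = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  effect_family <- match.arg(effect_family)
  if (!is.finite(pve) || pve <= 0 || pve >= 1)
    stop("pve must lie strictly inside (0, 1)")
  if (is.null(group_sizes)) {
    group_sizes <- switch(scenario,
                          I = c(10, 100, 1000),
                          II = c(10, 100, 1000),
                          III = c_large,
                          IV = integer(0))
  }
  if (is.null(group_var_shares)) {
    group_var_shares <- switch(scenario,
                               I = c(0.05, 0.15, 0.20, 0.60),
                               II = c(0.1, 0.2, 0.7),
                               III = c(0.2, 0.8),
                               IV = 1)
  }
  # scenarios I, III, IV include a final group of "all remaining SNPs"
  rest <- switch(scenario, I = TRUE, II = FALSE, III = TRUE, IV = TRUE)
  n_groups <- length(group_sizes) + as.integer(rest)
  if (length(group_var_shares) != n_groups)
    stop("group_var_shares must have one entry per effect group")
  if (abs(sum(group_var_shares) - 1) > 1e-8)
    stop("group_var_shares must sum to 1")
  structure(list(scenario = scenario, pve = pve,
                 effect_family = if (scenario == "IV") effect_family else "normal",
                 group_sizes = as.integer(group_sizes),
                 group_var_shares = as.numeric(group_var_shares),
                 rest_group = rest, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a phenotype on a genotype panel
#'
#' Randomly assigns SNPs to effect groups (sampling without replacement),
#' draws raw effects from the scenario's family, rescales each group's
#' effect block so the empirical variance of its genetic-value contribution
#' \eqn{var(X_g \beta_g)} equals exactly its target share of the total
#' genetic variance, and adds Gaussian noise orthogonalized against the
#' genetic values and rescaled so the realized PVE equals `spec$pve`
#' exactly. Consequently `var(y) = var(X\beta) + var(\epsilon)` holds
#' identically on the realized sample.
#'
#' @param gm a [genotype_matrix()] without missing values.
#' @param spec a [simulation_spec()].
#' @return An object of class `simulated_dataset`: list with `genotypes`,
#'   `beta_true`, `group_labels` (0 = null group in scenario II),
#'   `phenotype`, `realized_pve`, `group_shares`, `seed`.
#' @export
simulate_phenotype <- function(gm, spec) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "simulation_spec"))
  X <- gm$dosages
  if (anyNA(X)) stop("genotypes contain missing values; impute first")
  n <- nrow(X); p <- ncol(X)
  sizes <- spec$group_sizes
  if (sum(sizes) > p)
    stop("group sizes are infeasible for a panel with ", p, " SNPs")
  set.seed(spec$seed)

  # group assignment without replacement; group 0 = zero-effect (scenario II)
  labels <- integer(p)
  pool <- sample.int(p)
  off <- 0
  for (g in seq_along(sizes)) {
    labels[pool[(off + 1):(off + sizes[g])]] <- g
    off <- off + sizes[g]
  }
  if (spec$rest_group) {
    labels[pool[(off + 1):p]] <- length(sizes) + 1L
    if (off == p) stop("no SNPs left for the final effect group")
  }

  draw_effects <- function(m) {
    switch(spec$effect_family,
           normal = rnorm(m),
           t4 = rt(m, df = 4),
           laplace = rexp(m) * sample(c(-1, 1), m, replace = TRUE))
  }

  beta <- numeric(p)
  shares <- spec$group_var_shares
  n_groups <- length(shares)
  realized_shares <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    idx <- which(labels == g)
    raw <- draw_effects(length(idx))
    gv <- as.numeric(X[, idx, drop = FALSE] %*% raw)
    v <- var(gv)
    if (v <= 0) stop("degenerate genetic contribution in group ", g)
    beta[idx] <- raw * sqrt(shares[g] / v)
    realized_shares[g] <- shares[g]
  }

  G <- as.numeric(X %*% beta)
  vG <- var(G)
  eps <- rnorm(n)
  # orthogonalize against [1, G] so the variance bookkeeping is exact
  eps <- lm.fit(cbind(1, G), eps)$residuals
  eps <- eps * sqrt(vG * (1 - spec$pve) / (spec$pve * var(eps)))
  y <- G + eps

  structure(list(genotypes = gm, beta_true = beta, group_labels = labels,
                 phenotype = y, realized_pve = vG / var(y),
                 group_shares = realized_shares, seed = spec$seed,
                 spec = spec),
            class = "simulated_dataset")
}

#' Run a simulation study with Monte Carlo cross-validation
#'
#' For each scenario specification and replicate: simulates a fresh
#' phenotype, splits individuals into training (fraction `train_frac`) and
#' test sets at random, fits each method on the training data (genotypes
#' centered with training means), and scores predictions on the test set by
#' squared correlation and mean squared error.
#'
#' @param gm a [genotype_matrix()], or a list `list(n =, p =)` from which a
#'   panel is simulated.
#' @param specs a [simulation_spec()] or list of them.
#' @param n_replicates replicates per specification.
#' @param train_frac fraction of individuals in the training split.
#' @param methods named list of fitting backends; each is a function
#'   `f(y_train, X_train, X_test)` returning test-set predictions.
#' @param seed master seed; replicate seeds are derived deterministically.
#' @return Long-format data frame with columns `scenario`, `setting`,
#'   `pve`, `replicate`, `method`, `r2`, `mse`. A method failure is
#'   recorded as `NA` in its row and the study continues.
#' @export
run_simulation_study <- function(gm, specs, n_replicates = 20,
                                 train_frac = 0.8, methods, seed = 1) {
  if (inherits(specs, "simulation_spec")) specs <- list(specs)
  if (is.list(gm) && !inherits(gm, "genotype_matrix"))
    gm <- simulate_genotypes(gm$n, gm$p, seed = seed)
  stopifnot(length(methods) >= 1, !is.null(names(methods)))
  n <- nrow(gm$dosages)
  n_train <- floor(train_frac * n)
  if (n_train < 2 || n_train >= n) stop("train_frac leaves an empty split")

  rows <- list()
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    setting <- paste0(spec$scenario,
                      if (spec$scenario == "III") paste0(":c", spec$group_sizes[1]),
                      if (spec$scenario == "IV") paste0(":", spec$effect_family))
    for (rep_i in seq_len(n_replicates)) {
      rep_seed <- (seed * 1000L + s * 100L + rep_i) %% .Machine$integer.max
      spec_r <- spec
      spec_r$seed <- rep_seed
      sim <- simulate_phenotype(gm, spec_r)
      set.seed(rep_seed + 1L)
      train <- sort(sample.int(n, n_train))
      test <- setdiff(seq_len(n), train)
      ctr <- center_genotypes(gm$dosages[train, , drop = FALSE])
      Xte <- center_genotypes(gm$dosages[test, , drop = FALSE],
                              means = ctr$means)$X
      y_tr <- sim$phenotype[train]
      y_te <- sim$phenotype[test]
      for (mname in names(methods)) {
        yhat <- tryCatch(methods[[mname]](y_tr, ctr$X, Xte),
                         error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = spec$scenario, setting = setting, pve = spec$pve,
          replicate = rep_i, method = mname,
          r2 = if (is.null(yhat)) NA_real_ else r_squared(y_te, yhat),
          mse = if (is.null(yhat)) NA_real_ else mse(y_te, yhat),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
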