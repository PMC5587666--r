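test_that("plug-in prediction uses posterior means and training centering", {
  gm <- simulate_genotypes(80, 10, seed = 90)
  sim <- simulate_phenotype(gm, simulation_spec("IV", pve = 0.6, seed = 91))
  fit <- dpr_vb(sim$phenotype, gm$dosages, K = 2)

  # manual reconstruction of the plug-in rule on three individuals
  Xn <- gm$dosages[1:3, , drop = FALSE]
  manual <- fit$alpha_mean +
    as.numeric(sweep(Xn, 2, fit$x_center) %*% fit$beta_mean)
  expect_equal(predict(fit, Xn), manual)

  # zero effects predict the intercept everywhere
  fit0 <- fit
  fit0$beta_mean <- rep(0, 10)
  expect_equal(predict(fit0, Xn), rep(fit$alpha_mean, 3))

  # true coefficients and no noise give a perfect training R2
  y_perfect <- as.numeric(gm$dosages %*% sim$beta_true)
  fitp <- fit
  fitp$beta_mean <- sim$beta_true
  pred <- predict(fitp, gm$dosages)
  expect_equal(as.numeric(r_squared(y_perfect, pred)), 1)

  expect_error(predict(fit, Xn[, 1:3]), "columns")
})

test_that("accuracy metrics match hand computations", {
  y <- c(1, 2, 3); yhat <- c(1, 1, 2)
  expect_equal(as.numeric(r_squared(y, yhat)), 0.75)  # Pearson r = sqrt(3)/2
  expect_equal(mse(y, yhat), 2 / 3)

  set.seed(92)
  z <- rnorm(20)
  expect_equal(as.numeric(r_squared(z, z)), 1)
  expect_equal(mse(z, z), 0)
  expect_equal(as.numeric(r_squared(z, -z)), 1)
  expect_equal(mse(z, -z), 4 * mean(z^2))

  flat <- r_squared(z, rep(1, 20))
  expect_equal(as.numeric(flat), 0)
  expect_true(isTRUE(attr(flat, "degenerate")))
  expect_error(r_squared(rep(0, 5), rnorm(5)), "zero variance")
})

test_that("R2 is affine invariant but MSE is not", {
  set.seed(93)
  y <- rnorm(30); yhat <- 0.5 * y + rnorm(30)
  expect_equal(as.numeric(r_squared(y, 3 * yhat + 2)),
               as.numeric(r_squared(y, yhat)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(mse(y, 3 * yhat + 2), mse(y, yhat))))
})

test_that("cross-validation splits are seeded, disjoint and leak-free", {
  gm <- simulate_genotypes(60, 12, seed = 94)
  sim <- simulate_phenotype(gm, simulation_spec("IV", pve = 0.5, seed = 95))
  method <- function(y_tr, X_tr, X_te) {
    fit <- dpr_vb(y_tr, X_tr, K = 2, center = FALSE)
    predict(fit, X_te)
  }
  rep1 <- monte_carlo_cv(sim$phenotype, gm$dosages, method, n_splits = 4,
                         seed = 96, quantile_norm = TRUE)
  expect_equal(nrow(rep1$results), 4)
  for (s in 1:4) {
    expect_length(intersect(rep1$train_indices[[s]], rep1$splits[[s]]), 0)
    expect_setequal(c(rep1$train_indices[[s]], rep1$splits[[s]]), 1:60)
  }
  rep2 <- monte_carlo_cv(sim$phenotype, gm$dosages, method, n_splits = 4,
                         seed = 96, quantile_norm = TRUE)
  expect_identical(rep1$results, rep2$results)
  expect_identical(rep1$splits, rep2$splits)

  # mutation test: corrupting test-fold raw values must not change the
  # training-fold centering parameters of that split
  capture <- new.env()
  method2 <- function(y_tr, X_tr, X_te) {
    capture$means <- c(capture$means, list(colMeans(X_tr)))
    rep(mean(y_tr), nrow(X_te))
  }
  capture$means <- list()
  monte_carlo_cv(sim$phenotype, gm$dosages, method2, n_splits = 1,
                 seed = 97, quantile_norm = TRUE)
  means_clean <- capture$means[[1]]
  set.seed(97); test_idx <- setdiff(1:60, sort(sample.int(60, 48)))
  X_bad <- gm$dosages
  X_bad[test_idx, ] <- 0
  y_bad <- sim$phenotype
  y_bad[test_idx] <- seq(quantile(sim$phenotype, 0.3),
                         quantile(sim$phenotype, 0.7),
                         length.out = length(test_idx))
  capture$means <- list()
  monte_carlo_cv(y_bad, X_bad, method2, n_splits = 1, seed = 97,
                 quantile_norm = TRUE)
  expect_identical(capture$means[[1]], means_clean)
})

test_that("PVE summaries follow the draws", {
  expect_equal(pve_from_draws(rep(0, 50))$mean, 0)
  d <- c(rep(0.4, 50), rep(0.6, 50))
  s <- pve_from_draws(d)
  expect_equal(s$mean, 0.5)
  expect_equal(unname(s$interval), c(0.4, 0.6))
  expect_error(pve_from_draws(numeric(0)), "empty")

  # zero residual variance drives the per-draw PVE to one
  gm <- simulate_genotypes(50, 5, seed = 98)
  y <- as.numeric(gm$dosages %*% rep(1, 5))  # noiseless genetic phenotype
  fit <- dpr_mcmc(y, gm$dosages, K = 2, n_iter = 2000, burn_in = 500,
                  thin = 2, seed = 99, fix = list(sigma2e = 1e-8))
  expect_gt(fit$pve$mean, 0.99)
})

test_that("PIP counts assignments outside the background component", {
  gam <- cbind(c(1, 1, 1, 1), c(2, 2, 1, 2))  # 4 draws, 2 SNPs
  s2k <- matrix(rep(c(0.01, 1), each = 4), 4, 2)  # component 1 is background
  pip <- pip_from_draws(gam, s2k)
  expect_equal(pip, c(0, 0.75))

  # background identified per draw even when labels switch
  s2k_switch <- rbind(c(0.01, 1), c(1, 0.01), c(0.01, 1), c(0.01, 1))
  gam2 <- cbind(c(1, 2, 1, 1), c(2, 1, 2, 2))
  expect_equal(pip_from_draws(gam2, s2k_switch), c(0, 1))

  expect_warning(p1 <- pip_from_draws(gam[, 1, drop = FALSE],
                                      matrix(1, 4, 1)), "K = 1")
  expect_equal(p1, 0)
})

test_that("planted large effects earn higher PIPs than null SNPs", {
  gm <- simulate_genotypes(400, 100, seed = 100)
  spec <- simulation_spec("III", pve = 0.8, c_large = 10, seed = 101)
  sim <- simulate_phenotype(gm, spec)
  fit <- dpr_mcmc(sim$phenotype, gm$dosages, K = 4, n_iter = 3000,
                  burn_in = 600, thin = 3, seed = 102)
  large <- sim$group_labels == 1
  expect_gt(mean(fit$pip[large]), median(fit$pip[!large]))
})

test_that("GRM and effective segments behave like relatedness summaries", {
  gm <- simulate_genotypes(100, 400, maf_range = c(0.1, 0.5), seed = 103)
  X <- gm$dosages
  X[100, ] <- X[1, ]  # plant a duplicated individual
  grm <- compute_grm(X)
  expect_equal(grm, t(grm))
  expect_equal(mean(diag(grm)), 1, tolerance = 0.02)
  expect_equal(grm[1, 100], grm[1, 1], tolerance = 0.05)

  # unrelated individuals: off-diagonals concentrate near 0 with
  # variance about 1/p, so M_e is close to the number of independent SNPs
  gm2 <- simulate_genotypes(150, 500, maf_range = c(0.1, 0.5), seed = 104)
  grm2 <- compute_grm(gm2$dosages)
  off <- grm2[lower.tri(grm2)]
  expect_lt(abs(mean(off)), 0.02)
  me <- effective_segments(grm2)
  expect_gt(me, 250)
  expect_lt(me, 1000)
  expect_error(compute_grm(gm2$dosages[, 1, drop = FALSE]), "two SNPs")
})
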