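test_that("de-regression weights follow the closed formula", {
  # a perfectly accurate EBV with c = 1 gets the plain heritability ratio;
  # with c = 0 the record has no residual variance at all (infinite weight)
  expect_equal(deregression_weights(0.3, 1, c_weight = 1), (1 - 0.3) / 0.3)
  expect_equal(deregression_weights(0.3, 1, c_weight = 0), Inf)
  expect_equal(deregression_weights(0.5, sqrt(0.5), c_weight = 0.5),
               1 / 1.5, tolerance = 1e-12)
  expect_warning(w <- deregression_weights(0.5, c(0.8, 0)), "zero accuracy")
  expect_true(is.na(w[2]) && !is.na(w[1]))
  # equal accuracies give equal weights
  expect_equal(diff(range(deregression_weights(0.2, rep(0.7, 5)))), 0)
})

sim_train <- function(n = 80, p = 12, h2x = 0.6, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.4), n, p,
              dimnames = list(NULL, paste0("snp", 1:p)))
  b <- rnorm(p, sd = 0.5)
  g <- as.numeric(scale(X %*% b, scale = FALSE))
  y <- g + rnorm(n, sd = sd(g) * sqrt(1 / h2x - 1))
  list(X = X, y = y, b = b)
}

test_that("forcing all SNPs null gives constant GEBVs", {
  d <- sim_train()
  fit <- run_bayesc(d$X, d$y, config = bayesc_config(pi = 1, n_iter = 300,
                                                     burn_in = 50), seed = 3)
  expect_true(all(fit$snp_effects == 0))
  gebv <- predict_gebv(fit, d$X)
  expect_equal(diff(range(gebv)), 0)
})

test_that("single-SNP posterior mean matches the conjugate closed form", {
  set.seed(14)
  n <- 60
  x <- rbinom(n, 2, 0.5)
  y <- 0.8 * (x - mean(x)) + rnorm(n, sd = 1)
  s2e <- 1; s2a <- 4
  cfg <- bayesc_config(pi = 0, n_iter = 30000, burn_in = 2000,
                       fit_intercept = FALSE, update_sigma_a = FALSE,
                       update_sigma_e = FALSE,
                       s2_a = s2a)
  fit <- run_bayesc(matrix(x, ncol = 1, dimnames = list(NULL, "snp1")), y,
                    config = cfg, sigma2_a = s2a, maf_min = 0, seed = 15)
  xc <- x - mean(x)
  post_mean <- sum(xc * y) / (sum(xc^2) + s2e / s2a)
  post_sd <- sqrt(s2e / (sum(xc^2) + s2e / s2a))
  expect_equal(unname(fit$snp_effects[1]), post_mean,
               tolerance = 5 * post_sd / sqrt(28000) / abs(post_mean) + 0.01)
})

test_that("with pi = 0 and fixed variances the posterior mean is ridge", {
  set.seed(22)
  n <- 50; p <- 20
  X <- matrix(rbinom(n * p, 2, 0.5), n, p,
              dimnames = list(NULL, paste0("snp", 1:p)))
  b <- rnorm(p, sd = 0.3)
  Xc <- scale(X, scale = FALSE)
  y <- as.numeric(Xc %*% b) + rnorm(n)
  s2a <- 0.25; s2e <- 1
  cfg <- bayesc_config(pi = 0, n_iter = 40000, burn_in = 4000,
                       fit_intercept = FALSE, update_sigma_a = FALSE,
                       update_sigma_e = FALSE, s2_a = s2a)
  fit <- run_bayesc(X, y, config = cfg, sigma2_a = s2a, maf_min = 0,
                    seed = 23)
  ridge <- solve(crossprod(Xc) + diag(p) * s2e / s2a, crossprod(Xc, y))
  expect_lt(max(abs(fit$snp_effects - as.numeric(ridge))), 0.05)
  expect_gt(cor(fit$snp_effects, as.numeric(ridge)), 0.999)
})

test_that("null data recovers the prior inclusion frequency 1 - pi", {
  # In the weak-effect limit the indicator likelihood ratio is 1, so the
  # posterior inclusion frequency equals the prior exactly; with an
  # informative effect variance, null data push inclusion BELOW the prior
  # (the likelihood ratio has unit mean and the posterior is concave in it).
  set.seed(33)
  n <- 120; p <- 20
  X <- matrix(rbinom(n * p, 2, 0.5), n, p)
  y <- rnorm(n)  # no marker signal
  weak <- bayesc_config(pi = 0.95, n_iter = 6000, burn_in = 1000,
                        update_sigma_a = FALSE, s2_a = 1e-8)
  fit <- run_bayesc(X, y, config = weak, sigma2_a = 1, seed = 34)
  expect_lt(abs(mean(fit$inclusion_prob, na.rm = TRUE) - 0.05), 0.01)
  full <- run_bayesc(X, y, config = bayesc_config(pi = 0.95, n_iter = 6000,
                                                  burn_in = 1000),
                     sigma2_a = 1, seed = 35)
  expect_lt(mean(full$inclusion_prob, na.rm = TRUE), 0.1)
})

test_that("chains are bitwise reproducible from the seed", {
  d <- sim_train(seed = 5)
  cfg <- bayesc_config(n_iter = 500, burn_in = 100)
  f1 <- run_bayesc(d$X, d$y, config = cfg, seed = 99)
  f2 <- run_bayesc(d$X, d$y, config = cfg, seed = 99)
  expect_identical(f1$snp_effects, f2$snp_effects)
  expect_identical(f1$inclusion_prob, f2$inclusion_prob)
  f3 <- run_bayesc(d$X, d$y, config = cfg, seed = 100)
  expect_false(identical(f3$snp_effects, f1$snp_effects))
})

test_that("prediction is linear in genotypes and matched by SNP name", {
  fit <- structure(list(snp_effects = c(snp1 = 2, snp2 = 0),
                        inclusion_prob = c(snp1 = 1, snp2 = 0.1),
                        kept = c("snp1", "snp2"),
                        center = c(snp1 = 1, snp2 = 1)),
                   class = "bayesc_fit")
  Xp <- matrix(c(0, 2, 1, 1), 2, 2, dimnames = list(NULL, c("snp1", "snp2")))
  g <- predict_gebv(fit, Xp)
  expect_equal(g[2] - g[1], 4)  # one SNP, effect 2, genotype 2 vs 0
  Xs <- Xp[c(1, 1), ]
  expect_equal(diff(predict_gebv(fit, Xs)), 0)  # identical clones
  expect_error(predict_gebv(fit, matrix(0, 2, 1,
                                        dimnames = list(NULL, "other"))),
               "missing SNPs")
})

test_that("accuracy endpoints behave", {
  tbv <- rnorm(20)
  expect_equal(gebv_accuracy(tbv, tbv), 1)
  expect_equal(gebv_accuracy(-tbv, tbv), -1)
})

test_that("homogeneous weights reproduce the unweighted posterior", {
  d <- sim_train(n = 60, p = 8, seed = 6)
  cfg <- bayesc_config(pi = 0.5, n_iter = 15000, burn_in = 3000)
  f_unw <- run_bayesc(d$X, d$y, config = cfg, seed = 42)
  f_w <- run_bayesc(d$X, d$y, weights = rep(2, 60), config = cfg, seed = 43)
  expect_lt(max(abs(f_unw$snp_effects - f_w$snp_effects)), 0.12)
  expect_gt(cor(f_unw$snp_effects, f_w$snp_effects), 0.98)
})
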