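# Phylogenetic GLS with Pagel's lambda: transform, likelihood,
# optimization, inference and r-squared.

test_that("lambda transform scales off-diagonals only", {
  V <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(c(2, 2)))
  expect_equal(lambda_transform(V, 0.5), matrix(c(2, 0.5, 0.5, 2), 2, 2))
  expect_error(lambda_transform(V, -0.1), "non-negative")
  # a lambda beyond the PD limit is refused rather than regularized
  W <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  expect_error(lambda_transform(W, 1.2), "positive definite")
})

test_that("GLS with identity covariance reduces to ordinary least squares", {
  set.seed(3)
  n <- 20
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n)
  g <- gls_fit(y, X, diag(n))
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(unname(g$beta), unname(coef(ols)), tolerance = 1e-10)
  # constant response, intercept only
  g0 <- gls_fit(rep(3.5, n), X[, 1, drop = FALSE], diag(n))
  expect_equal(unname(g0$beta), 3.5)
  expect_equal(g0$rss, 0)
})

test_that("factorized GLS matches the explicit-inverse oracle", {
  # 4-taxon hand example on the balanced tree
  V <- vcv_matrix(balanced4(), c("A", "B", "C", "D"))
  y <- c(1, 2, 3, 4)
  X <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  g <- gls_fit(y, X, V)
  o <- gls_oracle(y, X, V)
  expect_equal(unname(g$beta), unname(o$beta), tolerance = 1e-10)
  expect_equal(g$log_likelihood, o$log_likelihood, tolerance = 1e-10)

  # random instances
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    tr <- random_tree(n)
    V <- vcv_matrix(tr)
    k <- sample(1:min(3, n - 2), 1)  # keep at least one residual df
    X <- cbind(1, matrix(rnorm(n * k), n, k))
    y <- rnorm(n, sd = 2)
    g <- gls_fit(y, X, V)
    o <- gls_oracle(y, X, V)
    expect_equal(unname(g$beta), unname(o$beta), tolerance = 1e-8)
    expect_equal(g$sigma2, o$sigma2, tolerance = 1e-8)
    expect_equal(g$log_likelihood, o$log_likelihood, tolerance = 1e-8)
  }

  # error reporting
  expect_error(gls_fit(1:4, cbind(a = rep(1, 4), b = rep(1, 4)), diag(4)),
               "rank deficient")
  expect_error(gls_fit(1:4, matrix(1, 4, 1), matrix(0, 4, 4)),
               "positive definite")
})

test_that("profile log-likelihood behaves as the transform dictates", {
  tr <- random_tree(8, seed = 5)
  V <- vcv_matrix(tr)
  set.seed(6)
  y <- rnorm(8)
  X <- matrix(1, 8, 1)
  # at lambda = 1 the profile equals the untransformed likelihood
  expect_equal(profile_loglik(1, y, X, V),
               gls_fit(y, X, V)$log_likelihood)
  # star tree: profile constant in lambda
  D <- diag(diag(V))
  lls <- vapply(c(0, 0.3, 0.7, 1), function(l) profile_loglik(l, y, X, D), 0)
  expect_equal(max(lls) - min(lls), 0)
  # data simulated under lambda = 1 prefer lambda = 1 over 0
  tr50 <- random_tree(50, seed = 77)
  y50 <- simulate_bm_traits(tr50, lambda = 1, sigma2 = 1, seed = 78)
  V50 <- vcv_matrix(tr50)
  X50 <- matrix(1, 50, 1)
  expect_gt(profile_loglik(1, y50, X50, V50),
            profile_loglik(0, y50, X50, V50))
})

test_that("ML lambda maximizes the profile over a grid", {
  sim <- simulate_regression_dataset(n_tips = 60, true_lambda = 0.6, seed = 21)
  V <- vcv_matrix(sim$tree, sim$traits$species)
  X <- cbind("(Intercept)" = 1,
             as.matrix(sim$traits[c("clutch_size", "foraging",
                                    "activity", "nest")]))
  fit <- fit_pgls(sim$traits$y, X, V)
  grid <- seq(0, 1, by = 0.05)
  lls <- vapply(grid, function(l) profile_loglik(l, sim$traits$y, X, V), 0)
  expect_true(all(fit$log_likelihood >= lls - 1e-6))
  expect_gte(fit$lambda_hat, 0)
  expect_lte(fit$lambda_hat, 1)
})

test_that("star covariance gives the OLS fit with lambda flagged", {
  set.seed(8)
  n <- 25
  X <- cbind(1, rbinom(n, 1, 0.5), rbinom(n, 1, 0.4))
  colnames(X) <- c("(Intercept)", "p1", "p2")
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(n)
  fit <- fit_pgls(y, X, diag(n))
  expect_false(fit$lambda_identifiable)
  expect_true(is.na(fit$lambda_hat))
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
  # ultrametric tree at lambda = 0: scalar covariance, still OLS
  tr <- random_tree(25, seed = 9)
  V <- vcv_matrix(tr)
  y2 <- rnorm(25)
  f0 <- fit_pgls(y2, X, V, lambda_mode = "fixed", lambda_value = 0)
  ols2 <- lm(y2 ~ X[, 2] + X[, 3])
  expect_equal(unname(f0$beta), unname(coef(ols2)), tolerance = 1e-10)
})

test_that("rescaling the response rescales beta and se but nothing else", {
  sim <- simulate_regression_dataset(n_tips = 40, true_lambda = 0.7, seed = 31)
  V <- vcv_matrix(sim$tree, sim$traits$species)
  X <- cbind("(Intercept)" = 1,
             as.matrix(sim$traits[c("clutch_size", "foraging",
                                    "activity", "nest")]))
  f1 <- fit_pgls(sim$traits$y, X, V)
  f2 <- fit_pgls(2 * sim$traits$y, X, V)
  expect_equal(f2$beta, 2 * f1$beta, tolerance = 1e-10)
  expect_equal(f2$se, 2 * f1$se, tolerance = 1e-10)
  expect_equal(f2$lambda_hat, f1$lambda_hat, tolerance = 1e-6)
  expect_equal(f2$t_stat, f1$t_stat, tolerance = 1e-8)
  expect_equal(f2$p_two_sided, f1$p_two_sided, tolerance = 1e-8)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-8)
})

test_that("coefficient tests divide estimates by standard errors", {
  # ratios of the published coefficient/SE pairs
  expect_equal(round(-8.337654 / 2.552405, 4), -3.2666)
  fit <- structure(list(beta = c(-8.337654, -3.497337),
                        se = c(2.552405, 1.695883),
                        coef_names = c("clutch", "activity"),
                        n_taxa = 33L, k = 5L,
                        df_convention = "n_taxa", tail = "one"),
                   class = "pgls_fit")
  tab <- coefficient_tests(fit)
  expect_equal(round(tab$t, 4), c(-3.2666, -2.0623))
  expect_equal(tab$marker, c("**", "*"))
  # two-sided at the same df
  tab2 <- coefficient_tests(fit, tail = "two")
  expect_equal(tab2$p, 2 * tab$p_one_sided)
  # zero coefficient: t = 0, two-sided p = 1
  fit0 <- structure(list(beta = 0, se = 1, coef_names = "x",
                         n_taxa = 20L, k = 1L,
                         df_convention = "n_minus_k", tail = "two"),
                    class = "pgls_fit")
  tab0 <- coefficient_tests(fit0)
  expect_equal(tab0$t, 0)
  expect_equal(tab0$p_two_sided, 1)
  fitz <- structure(list(beta = 1, se = 0, coef_names = "x",
                         n_taxa = 20L, k = 1L,
                         df_convention = "n_taxa", tail = "two"),
                    class = "pgls_fit")
  expect_error(coefficient_tests(fitz), "degenerate")
})

test_that("whitened-space r-squared matches its classical limits", {
  set.seed(13)
  n <- 30
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  beta <- c(1, 3, -2)
  # perfect fit
  y_exact <- drop(X %*% beta)
  expect_equal(pgls_r_squared(y_exact, X, diag(n)), 1)
  # intercept-only model explains nothing
  y <- y_exact + rnorm(n)
  expect_equal(pgls_r_squared(y, X[, 1, drop = FALSE], diag(n)), 0)
  # identity covariance equals the OLS coefficient of determination
  expect_equal(pgls_r_squared(y, X, diag(n)), ols_r2_oracle(y, X),
               tolerance = 1e-10)
  expect_error(pgls_r_squared(rep(1, n), X, diag(n)), "degenerate")
})

test_that("lambda and coefficients agree with an independent GLS oracle", {
  skip_if_not_installed("nlme")
  sim <- simulate_regression_dataset(n_tips = 80, true_lambda = 0.7,
                                     sigma2 = 5, seed = 41)
  V <- vcv_matrix(sim$tree, sim$traits$species)
  X <- cbind("(Intercept)" = 1,
             as.matrix(sim$traits[c("clutch_size", "foraging",
                                    "activity", "nest")]))
  fit <- fit_pgls(sim$traits$y, X, V)
  d <- sim$traits
  g <- nlme::gls(y ~ clutch_size + foraging + activity + nest, data = d,
                 correlation = ape::corPagel(0.5, phy = sim$tree,
                                             form = ~species),
                 method = "ML")
  lam_nlme <- coef(g$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(unname(fit$beta), unname(coef(g)), tolerance = 1e-4)
  expect_equal(fit$lambda_hat, unname(lam_nlme), tolerance = 0.01)
  expect_equal(fit$log_likelihood, as.numeric(logLik(g)), tolerance = 1e-4)
})
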