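test_that("transform selection follows the declared value domain", {
  expect_identical(select_transform(c(8, 10, 12), "positive")$name, "log")
  expect_identical(select_transform(c(-1, 0, 2), "real")$name, "identity")
  expect_identical(select_transform(c(0, 1, 1, 0), "binary")$name, "logit")
  tr <- select_transform(c(0, 0.04, 0.3, 1), "unit-interval")
  expect_identical(tr$name, "logit")
  # boundary clipping keeps transformed values finite; eps = half the
  # smallest nonzero distance from {0, 1}
  expect_true(all(is.finite(tr$fwd(c(0, 0.04, 0.3, 1)))))
  expect_equal(tr$eps, 0.02)
  # floor at 1e-3
  tr2 <- select_transform(c(0, 1e-5, 0.5), "unit-interval")
  expect_equal(tr2$eps, 1e-3)
  expect_error(select_transform(c(-2, 3), "positive"), "non-positive")
  expect_error(select_transform(c(-0.1, 0.5), "unit-interval"),
               "outside")
})

test_that("lasso path obeys the KKT bound at lambda_max and the
           soft-threshold closed form on orthonormal designs", {
  set.seed(1)
  n <- 64
  # all-zero solution at and above lambda_max
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rnorm(n)
  path <- fit_lasso_path(X, y)
  expect_true(all(path$beta[, 1] == 0))

  # orthonormal (in the 1/n inner product) design: beta_j(lambda) =
  # S(x_j'y/n, lambda) exactly. Zero-mean, unit-population-variance
  # columns make the internal standardization an exact no-op.
  Z <- matrix(rnorm(n * 6), n, 6)
  Zc <- sweep(Z, 2, colMeans(Z))
  Q <- qr.Q(qr(Zc)) * sqrt(n)
  colnames(Q) <- paste0("q", 1:6)
  beta_true <- c(3, -2, 1, 0.5, 0, 0)
  y2 <- drop(Q %*% beta_true) + rnorm(n, 0, 0.3)
  p2 <- fit_lasso_path(Q, y2)
  z <- drop(crossprod(Q, y2 - mean(y2))) / n
  for (i in seq(1, length(p2$lambda), by = 10)) {
    closed <- sign(z) * pmax(abs(z) - p2$lambda[i], 0)
    expect_equal(unname(p2$beta[, i]), unname(closed), tolerance = 1e-6)
  }

  # KKT subgradient conditions hold at every reported path point
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2,
              sqrt(colMeans(sweep(X, 2, colMeans(X))^2)), "/")
  for (i in seq_along(path$lambda)) {
    bs <- path$beta_std[, i]
    expect_lt(kkt_violation(Xs, y - mean(y), bs, path$lambda[i]), 1e-5)
  }
})

test_that("lasso path matches the glmnet convex-solver oracle on
           5-covariate problems", {
  skip_if_not_installed("glmnet")
  set.seed(2)
  for (rep in 1:3) {
    n <- 50 + 10 * rep
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    X[, 2] <- X[, 1] * 0.6 + X[, 2] * 0.8   # correlated pair
    y <- drop(X %*% c(1.5, -1, 0.5, 0, 0)) + rnorm(n)
    path <- fit_lasso_path(X, y)
    g <- glmnet::glmnet(X, y, lambda = path$lambda, standardize = TRUE,
                        thresh = 1e-12)
    expect_lt(max(abs(as.matrix(g$beta) - path$beta)), 1e-5)
    expect_lt(max(abs(g$a0 - path$a0)), 1e-5)
  }
})

test_that("cross-validated penalty selection is calibrated on noise and
           ranks a strong predictor first", {
  set.seed(3)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  # pure-noise response: best CV R^2 stays at or below zero + MC margin
  cv0 <- cross_validate_penalty(X, rnorm(n), seed = 1)
  expect_lt(max(cv0$cv_r2), 0.05)

  # one strong predictor: first in inclusion order, CV curve rises then
  # declines past the optimum (overfitting at small penalties)
  y <- 2 * X[, "v3"] + rnorm(n)
  cv1 <- cross_validate_penalty(X, y, seed = 1)
  expect_identical(cv1$path$inclusion_order$covariate[1], "v3")
  expect_gt(cv1$r2_opt, 0.5)
  i_opt <- which(cv1$lambda == cv1$lambda_opt)
  expect_gt(cv1$cv_r2[i_opt], cv1$cv_r2[length(cv1$lambda)])
  expect_gte(cv1$lambda_1se, cv1$lambda_opt)

  # same seed, same folds, same optimum
  cv2 <- cross_validate_penalty(X, y, seed = 1)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_identical(cv1$lambda_opt, cv2$lambda_opt)
  expect_error(cross_validate_penalty(X[1:10, ], y[1:10], folds = 5),
               "fewer than 3")
})

test_that("generalized R-squared reduces to classical R-squared for
           Gaussian fits", {
  expect_equal(generalized_r2(-10, -10, 25), 0)
  expect_error(generalized_r2(-1, -1, 0), "positive")
  # held-out model can be worse than the null: negative by definition
  expect_lt(generalized_r2(-12, -10, 30), 0)

  set.seed(4)
  x <- rnorm(40)
  y <- 1 + 0.8 * x + rnorm(40)
  fit <- lm(y ~ x)
  null <- lm(y ~ 1)
  n <- 40
  # profiled Gaussian log-likelihoods
  ll <- function(rss) -n / 2 * (log(2 * pi * rss / n) + 1)
  r2_gen <- generalized_r2(ll(sum(fit$residuals^2)),
                           ll(sum(null$residuals^2)), n)
  expect_equal(r2_gen, summary(fit)$r.squared, tolerance = 1e-8)
})

test_that("variance attribution matches brute-force covariance arithmetic
           and sums to the total", {
  set.seed(5)
  n <- 200
  # orthogonal groups: shares equal each group's marginal variance ratio
  X <- cbind(a = rep(c(-1, 1), n / 2), b = rep(c(-1, 1), each = n / 2))
  beta <- c(a = 2, b = 1)
  y <- drop(X %*% beta) + rnorm(n)
  att <- attribute_variance_components(X, beta,
                                       c(a = "genetic", b = "transcriptomic"),
                                       y)
  expect_equal(sum(att$shares), att$total_r2, tolerance = 1e-8)
  expect_equal(unname(att$shares["genetic"]),
               var(X[, "a"] * 2) / var(y), tolerance = 1e-8)

  # correlated two-group fixture against direct covariance sums
  Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("u", "v", "w")))
  Z[, 2] <- 0.7 * Z[, 1] + 0.3 * Z[, 2]
  bz <- c(u = 1, v = -0.5, w = 0.25)
  yz <- drop(Z %*% bz) + rnorm(n)
  gz <- c(u = "genetic", v = "transcriptomic", w = "transcriptomic")
  az <- attribute_variance_components(Z, bz, gz, yz)
  r_g <- scale(Z[, "u", drop = FALSE] %*% bz["u"], scale = FALSE)
  r_t <- scale(Z[, c("v", "w")] %*% bz[c("v", "w")], scale = FALSE)
  expect_equal(unname(az$shares["genetic"]),
               (var(drop(r_g)) + cov(drop(r_g), drop(r_t))) / var(yz),
               tolerance = 1e-10)
  expect_equal(sum(az$shares), az$total_r2, tolerance = 1e-8)

  # single nonzero group receives the full explained variance
  b1 <- c(u = 1, v = 0, w = 0)
  a1 <- attribute_variance_components(Z, b1, gz, yz)
  expect_equal(unname(a1$shares["transcriptomic"]), 0)
  expect_error(attribute_variance_components(Z, bz, gz, rep(1, n)),
               "zero-variance")
})

test_that("the end-to-end phenotype model recovers a strong simulated
           signal", {
  sim <- simulate_cohort(tiny_config(), seed = 11)
  fit <- fit_phenotype_model(sim$bundle, "ring_sideroblasts", n_pcs = 5,
                             seed = 1)
  expect_identical(fit$transform, "logit")
  # SF3B1 drives ring sideroblasts in the generator
  expect_true("SF3B1" %in%
                fit$cv$path$inclusion_order$covariate[1:3])
  expect_equal(sum(fit$attribution$shares), fit$attribution$total_r2,
               tolerance = 1e-8)
  expect_error(fit_phenotype_model(sim$bundle, "nope"), "unknown")
})
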