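test_that("run_pca matches a dense eigendecomposition oracle and orders
           components", {
  set.seed(1)
  # instances up to 50 x 30 against the covariance eigensolver
  for (dims in list(c(4, 3), c(20, 10), c(50, 30))) {
    Y <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    k <- dims[2] - 1
    pc <- run_pca(Y, k)
    Yc <- t(Y) - rep(colMeans(t(Y)), each = ncol(Y))
    eig <- eigen(crossprod(Yc) / (ncol(Y) - 1), symmetric = TRUE)
    for (j in seq_len(k)) {
      v <- eig$vectors[, j]
      if (v[which.max(abs(v))] < 0) v <- -v
      expect_equal(unname(pc$loadings[, j]), v, tolerance = 1e-8)
      expect_equal(unname(pc$scores[, j]), unname(drop(Yc %*% v)),
                   tolerance = 1e-8)
    }
    expect_equal(sum(pc$var_frac), 1)
    expect_true(all(diff(pc$var_frac) <= 1e-12))
    # scores of distinct components are uncorrelated
    if (k > 1)
      expect_lt(max(abs(cor(pc$scores)[lower.tri(diag(k))])), 1e-8)
  }

  # rank-1 matrix: the first component carries all the variance
  Y1 <- outer(rnorm(10), rnorm(6))
  pc1 <- run_pca(Y1, 2)
  expect_equal(pc1$var_frac[1], 1, tolerance = 1e-12)
  expect_error(run_pca(Y1, 11), "k must be")
})

test_that("design matrix applies the recurrence threshold and carries
           group labels", {
  b <- tiny_bundle()
  d <- build_design_matrix(b, min_recurrence = 5)
  counts <- colSums(b$lesions)
  kept <- names(counts)[counts >= 5]
  expect_setequal(names(d$groups)[d$groups %in% c("genetic",
                                                  "cytogenetic")], kept)
  expect_identical(unname(d$groups[c("(Intercept)", "disease", "sex",
                                     "age")]),
                   c("intercept", "disease", "demographic", "demographic"))
  # disease indicator requires controls
  b0 <- simulate_cohort(tiny_config(n_normals = 0), seed = 2)$bundle
  expect_warning(d0 <- build_design_matrix(b0), "disease indicator")
  expect_false("disease" %in% colnames(d0$X))
  # duplicated lesion columns are named in the rank-deficiency error
  b2 <- b
  b2$lesions <- cbind(b$lesions, dup = b$lesions[, which.max(counts)])
  b2$lesion_class <- c(b$lesion_class, dup = "genetic")
  expect_error(build_design_matrix(b2), "collinear")
})

test_that("per-gene fits recover exact and simulated coefficients and are
           order-invariant", {
  b <- tiny_bundle()
  d <- build_design_matrix(b)
  lesion <- names(d$groups)[d$groups == "genetic"][1]
  # a gene equal to a design column is fitted exactly
  b$expression["G0001", ] <- d$X[colnames(b$expression), lesion]
  fits <- fit_gene_models(b$expression, d)
  expect_equal(unname(fits$coef["G0001", lesion]), 1, tolerance = 1e-10)
  expect_equal(unname(fits$sigma2["G0001"]), 0, tolerance = 1e-18)
  expect_equal(fits$df, nrow(d$X) - ncol(d$X))

  # known coefficient at low noise is recovered within 3 SE
  set.seed(3)
  b$expression["G0002", ] <- 5 +
    0.8 * d$X[colnames(b$expression), lesion] +
    rnorm(ncol(b$expression), 0, 0.1)
  fits <- fit_gene_models(b$expression, d)
  se <- 0.1 * fits$se_unscaled[lesion]
  expect_lt(abs(fits$coef["G0002", lesion] - 0.8), 3 * se)

  # consistent sample permutation leaves fits unchanged
  perm <- sample(colnames(b$expression))
  d2 <- d
  d2$X <- d$X[perm, ]
  d2$samples <- perm
  fits2 <- fit_gene_models(b$expression[, perm], d2)
  expect_equal(fits2$coef, fits$coef, tolerance = 1e-10)
})

test_that("moderated statistics match the limma empirical-Bayes
           cross-check", {
  skip_if_not_installed("limma")
  set.seed(4)
  n <- 50; G <- 600
  X <- cbind(`(Intercept)` = 1, les = rbinom(n, 1, 0.3),
             age = rnorm(n))
  rownames(X) <- paste0("s", 1:n)
  sig2 <- 6 * 0.3 / rchisq(G, 6)
  Y <- 2 + matrix(rnorm(G * n, 0, sqrt(rep(sig2, n))), G, n)
  dimnames(Y) <- list(paste0("g", 1:G), rownames(X))
  d <- structure(list(X = X,
                      groups = c(`(Intercept)` = "intercept",
                                 les = "genetic", age = "demographic"),
                      samples = rownames(X)), class = "design_matrix")
  fits <- fit_gene_models(Y, d)
  mod <- moderate_statistics(fits)
  eb <- limma::eBayes(limma::lmFit(Y, X))
  expect_equal(mod$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(mod$s0_sq, eb$s2.prior, tolerance = 1e-8)
  expect_equal(unname(mod$t[, "les"]), unname(eb$t[, "les"]),
               tolerance = 1e-10)
  expect_equal(unname(mod$s_tilde_sq), unname(eb$s2.post),
               tolerance = 1e-10)
  # posterior variances lie between the sample and prior variances
  lo <- pmin(fits$sigma2, mod$s0_sq)
  hi <- pmax(fits$sigma2, mod$s0_sq)
  expect_true(all(mod$s_tilde_sq >= lo - 1e-12 &
                    mod$s_tilde_sq <= hi + 1e-12))
})

test_that("infinite-d0 limit pins every posterior variance at the prior", {
  set.seed(5)
  n <- 30; G <- 50
  X <- cbind(`(Intercept)` = 1, les = rbinom(n, 1, 0.4))
  rownames(X) <- paste0("s", 1:n)
  # homoscedastic genes: log-variance spread below its chi-square floor
  Y <- matrix(rnorm(G * n, 0, 1), G, n,
              dimnames = list(paste0("g", 1:G), rownames(X)))
  d <- structure(list(X = X, groups = c(`(Intercept)` = "intercept",
                                        les = "genetic"),
                      samples = rownames(X)), class = "design_matrix")
  fits <- fit_gene_models(Y, d)
  fits$sigma2 <- rep(1.3, G)       # identical variances: evar <= 0
  mod <- moderate_statistics(fits)
  expect_identical(mod$d0, Inf)
  expect_equal(unname(mod$s_tilde_sq), rep(mod$s0_sq, G))
})

test_that("BH adjustment equals the direct step-up computation", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.037), 0.037)
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (m in c(1, 7, 100, 503)) {
    p <- runif(m)^2
    expect_equal(adjust_fdr(p), bh_stepup(p), tolerance = 1e-12)
  }
  # q-values are monotone in p-value rank
  p <- runif(200)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("genomic R-squared matches explicit least-squares arithmetic", {
  # a gene that IS the lesion column, with no other covariates: the
  # genomic block explains everything
  les6 <- c(0, 0, 0, 1, 1, 1)
  X6 <- cbind(`(Intercept)` = 1, M = les6)
  rownames(X6) <- paste0("t", 1:6)
  d6 <- structure(list(X = X6, groups = c(`(Intercept)` = "intercept",
                                          M = "genetic"),
                       samples = rownames(X6)), class = "design_matrix")
  Y6 <- matrix(les6, 1, 6, dimnames = list("g1", rownames(X6)))
  f6 <- fit_gene_models(Y6, d6)
  expect_equal(unname(per_gene_variance_explained(f6)$r2_genomic), 1,
               tolerance = 1e-12)
  # the full-model R^2 of a perfectly fitted gene is also 1 when other
  # covariates partially track the lesion
  b <- tiny_bundle()
  d <- build_design_matrix(b)
  lesion <- names(d$groups)[d$groups == "genetic"][1]
  b$expression["G0001", ] <- d$X[colnames(b$expression), lesion]
  fits <- fit_gene_models(b$expression, d)
  r2 <- per_gene_variance_explained(fits)
  expect_equal(unname(r2$r2_full["G0001"]), 1, tolerance = 1e-9)
  expect_true(all(r2$r2_genomic >= 0 & r2$r2_genomic <= 1))
  expect_true(all(r2$r2_genomic <= r2$r2_full + 1e-12))

  # hand-computable 6-sample, 1-lesion example
  les <- c(0, 0, 0, 1, 1, 1)
  y <- c(1, 2, 3, 5, 6, 7)
  rss_full <- sum(lm(y ~ les)$residuals^2)
  rss_red <- sum(lm(y ~ 1)$residuals^2)
  tss <- sum((y - mean(y))^2)
  X <- cbind(`(Intercept)` = 1, M = les)
  rownames(X) <- paste0("s", 1:6)
  dd <- structure(list(X = X, groups = c(`(Intercept)` = "intercept",
                                         M = "genetic"),
                       samples = rownames(X)), class = "design_matrix")
  Y <- matrix(y, 1, 6, dimnames = list("g1", rownames(X)))
  f <- fit_gene_models(Y, dd)
  expect_equal(unname(per_gene_variance_explained(f)$r2_genomic),
               (rss_red - rss_full) / tss, tolerance = 1e-12)
})

test_that("target sets honour the FDR threshold and the permutation check
           is reproducible", {
  b <- tiny_bundle()
  d <- build_design_matrix(b)
  gft <- gene_fit_table(fit_gene_models(b$expression, d))
  empty <- extract_target_sets(gft, fdr = 0)
  expect_true(all(vapply(empty, nrow, 0L) == 0))
  ts <- extract_target_sets(gft, fdr = 0.05)
  expect_true("disease" %in% names(ts))
  for (s in ts) expect_true(all(s$q < 0.05))

  expect_error(permutation_null_check(b$expression, d, 0, seed = 1),
               "n_perm")
  r1 <- permutation_null_check(b$expression, d, 3, seed = 11)
  r2 <- permutation_null_check(b$expression, d, 3, seed = 11)
  expect_identical(r1, r2)
  # identity scheme reproduces the observed discovery counts
  obs <- permutation_null_check(b$expression, d, 1, seed = 1,
                                scheme = "identity")
  genomic <- names(d$groups)[d$groups %in% c("genetic", "cytogenetic")]
  expect_identical(obs$n_disc_t,
                   sum(gft$q[, genomic] < 0.05, na.rm = TRUE))
})

test_that("predicted expression is additive across lesions by model
           construction", {
  b <- tiny_bundle()
  d <- build_design_matrix(b)
  fits <- fit_gene_models(b$expression, d)
  lesions <- names(d$groups)[d$groups == "genetic"][1:2]
  base <- d$X[1, , drop = FALSE] * 0
  base[, "(Intercept)"] <- 1
  single1 <- single2 <- double <- base
  single1[, lesions[1]] <- 1
  single2[, lesions[2]] <- 1
  double[, lesions] <- 1
  pred <- function(x) drop(fits$coef %*% t(x))
  expect_equal(pred(double),
               pred(single1) + pred(single2) - pred(base),
               tolerance = 1e-10)
})
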