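test_that("Harrell's C handles the canonical hand cases", {
  # risk perfectly anti-ordered with uncensored times
  tt <- 1:5
  expect_equal(harrells_c(tt, rep(1, 5), 5:1), 1)
  # constant risk: every comparable pair is a tie
  expect_equal(harrells_c(tt, rep(1, 5), rep(0, 5)), 0.5)
  # worked 3-sample example: comparable pairs (1,2), (1,3), (2,3)
  expect_equal(harrells_c(c(1, 2, 3), c(1, 1, 0), c(3, 1, 2)), 2 / 3)
  expect_error(harrells_c(c(1, 2), c(0, 0), c(1, 2)), "comparable")
})

test_that("Harrell's C equals the O(n^2) brute-force oracle on 200 random
           censored instances", {
  for (s in 1:200) {
    inst <- rand_surv_instance(n = sample(5:40, 1), seed = s)
    c_fast <- tryCatch(harrells_c(inst$time, inst$status, inst$risk),
                       error = function(e) NA_real_)
    c_brut <- tryCatch(brute_force_c(inst$time, inst$status, inst$risk),
                       error = function(e) NA_real_)
    expect_identical(c_fast, c_brut)
  }
})

test_that("ridge Cox at tau = 0 matches the partial-likelihood MLE oracle
           with Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(1)
  for (rep in 1:3) {
    n <- 120
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(paste0("s", 1:n), paste0("v", 1:4)))
    tt <- ceiling(rexp(n, exp(drop(X %*% c(0.8, -0.5, 0.3, 0)))) * 20)
    st <- rbinom(n, 1, 0.75)
    fit <- fit_ridge_cox(X, tt, st, tau = 0)
    cp <- survival::coxph(survival::Surv(tt, st) ~ X,
                          ties = "breslow")
    expect_lt(max(abs(fit$coef - coef(cp))), 1e-6)
    expect_lte(fit$grad_norm, 1e-8)
  }
})

test_that("extreme ridge shrinks every coefficient to zero and C to 0.5", {
  set.seed(2)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  tt <- rexp(n, exp(X[, 1]))
  fit <- fit_ridge_cox(X, tt, rep(1, n), tau = 1e8)
  expect_lt(max(abs(fit$coef)), 1e-4)
  # in the exact infinite-penalty limit all risks tie and C is 1/2
  fit_inf <- fit_ridge_cox(X, tt, rep(1, n), tau = Inf)
  expect_identical(unname(fit_inf$coef), numeric(3))
  expect_equal(harrells_c(tt, rep(1, n), fit_inf$risk), 0.5)
  expect_error(fit_ridge_cox(X, tt, rep(0, n), tau = 0), "2 events")
})

test_that("ridge Cox recovers a known log-hazard ratio within 3 SE", {
  cfg <- sim_config(n_samples = 2000, n_normals = 0, n_genes = 50,
                    censor_rate = 0.25)
  cfg$surv_coef <- list(genetic = c(SF3B1 = 1))
  X <- simulate_mutation_matrix(cfg, seed = 4)
  sv <- simulate_survival(list(genetic = X[, "SF3B1", drop = FALSE]),
                          cfg, seed = 4)
  fit <- fit_ridge_cox(X[, "SF3B1", drop = FALSE], sv$survival$time,
                       sv$survival$status, tau = 0)
  se <- sqrt(1 / sum(sv$survival$status) * 4)  # conservative bound
  expect_lt(abs(unname(fit$coef) - 1), 3 * se)
})

test_that("risk-variance decomposition is exact and reduces to plain
           variances for orthogonal groups", {
  set.seed(5)
  n <- 300
  # orthogonal blocks by construction
  A <- matrix(rnorm(n * 2), n, 2)
  A <- qr.Q(qr(sweep(A, 2, colMeans(A)))) * sqrt(n)
  B <- matrix(rnorm(n * 2), n, 2)
  B <- B - A %*% solve(crossprod(A), crossprod(A, B))
  B <- sweep(B, 2, colMeans(B))
  X <- cbind(A, B)
  colnames(X) <- c("a1", "a2", "b1", "b2")
  tt <- rexp(n, exp(0.5 * X[, 1]))
  fit <- fit_ridge_cox(X, tt, rep(1, n), tau = 1,
                       groups = c(a1 = "genetic", a2 = "genetic",
                                  b1 = "transcriptomic",
                                  b2 = "transcriptomic"))
  dec <- decompose_risk_variance(fit)
  expect_equal(sum(dec$components), dec$var_risk, tolerance = 1e-10)
  expect_equal(unname(dec$components),
               unname(apply(dec$risk_by_group, 2, var)),
               tolerance = 1e-8)

  # correlated groups: components equal brute-force covariance sums and
  # still sum exactly
  Xc <- cbind(X[, 1:2], 0.8 * X[, 1:2] + matrix(rnorm(n * 2), n, 2))
  colnames(Xc) <- colnames(X)
  fit2 <- fit_ridge_cox(Xc, tt, rep(1, n), tau = 1,
                        groups = c(a1 = "genetic", a2 = "genetic",
                                   b1 = "transcriptomic",
                                   b2 = "transcriptomic"))
  dec2 <- decompose_risk_variance(fit2)
  R <- dec2$risk_by_group
  expect_equal(unname(dec2$components[1]),
               var(R[, 1]) + cov(R[, 1], R[, 2]), tolerance = 1e-12)
  expect_equal(sum(dec2$components), dec2$var_risk, tolerance = 1e-10)

  fit_one <- fit_ridge_cox(X[, 1:2], tt, rep(1, n), tau = 1,
                           groups = c(a1 = "genetic", a2 = "genetic"))
  expect_error(decompose_risk_variance(fit_one), "2 covariate groups")
})

test_that("Kaplan-Meier terciles match hand product-limit arithmetic and
           flag ordering", {
  # 9 samples, no censoring, 3 cleanly separated risk groups
  tt <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  st <- rep(1, 9)
  risk <- c(9, 8, 7, 6, 5, 4, 3, 2, 1)
  km <- kaplan_meier_terciles(risk, tt, st)
  high <- km$curves[km$curves$tercile == "high", ]
  # product-limit by hand: 3 samples, events at 1, 2, 3
  expect_equal(high$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(high$time, c(1, 2, 3))
  expect_true(km$ordered)
  expect_error(kaplan_meier_terciles(rep(1, 9), tt, st), "identical")
  expect_error(kaplan_meier_terciles(risk[1:5], tt[1:5], st[1:5]),
               "at least 9")
  # no events: curves stay flat at 1
  km0 <- kaplan_meier_terciles(risk, tt, rep(0, 9))
  expect_true(all(km0$curves$surv == 1) || nrow(km0$curves) == 0)
})

test_that("cross-validated concordance is deterministic and near 0.5 on
           pure noise", {
  set.seed(6)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  tt <- rexp(n)
  st <- rbinom(n, 1, 0.7)
  r1 <- cross_validated_concordance(X, tt, st, seed = 3,
                                    tau_grid = c(1, 10))
  r2 <- cross_validated_concordance(X, tt, st, seed = 3,
                                    tau_grid = c(1, 10))
  expect_identical(r1$fold_id, r2$fold_id)
  expect_identical(r1$fold_c, r2$fold_c)
  expect_equal(r1$mean_c, mean(r1$fold_c))
  expect_gt(r1$mean_c, 0.4)
  expect_lt(r1$mean_c, 0.6)
})

test_that("genotype-predicted expression equals the fitted genomic
           regression and flags design mismatch", {
  sim <- simulate_cohort(tiny_config(), seed = 7)
  b <- sim$bundle
  d <- build_design_matrix(b)
  pca <- run_pca(b$expression, 5)
  pe <- predict_expression_from_genotype(pca, d)
  # an all-wild-type disease sample's prediction is intercept + disease
  wt <- rownames(d$X)[rowSums(d$X[, d$groups %in% c("genetic",
                                                    "cytogenetic"),
                                  drop = FALSE]) == 0]
  expect_gt(length(wt), 0)
  # genomic-only model: intercept is the whole prediction for wild type
  expect_equal(unname(pe$scores[wt[1], ]),
               unname(pe$coef["(Intercept)", ]), tolerance = 1e-10)
  expect_false("disease" %in% rownames(pe$coef))
  expect_error(predict_expression_from_genotype(
    pca, d, newdata = matrix(0, 2, 2,
                             dimnames = list(NULL, c("x", "y")))),
    "lacks the trained design columns")
})

test_that("predictor-class comparison reports one row per class and is
           seed-stable", {
  sim <- simulate_cohort(tiny_config(), seed = 8)
  cmp <- compare_predictor_classes(sim$bundle,
                                   classes = c("genetic", "demographic"),
                                   n_pcs = 4, folds = 3, seed = 5)
  expect_identical(cmp$class, c("genetic", "demographic"))
  expect_true(all(cmp$mean_c >= 0 & cmp$mean_c <= 1))
  cmp2 <- compare_predictor_classes(sim$bundle,
                                    classes = c("genetic", "demographic"),
                                    n_pcs = 4, folds = 3, seed = 5)
  expect_identical(cmp$mean_c, cmp2$mean_c)
  expect_error(compare_predictor_classes(sim$bundle, classes = "karyo"),
               "unknown predictor class")
})
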