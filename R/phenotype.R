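#' Choose the range-dependent response transform
#'
#' Blood and bone-marrow counts enter the penalized models on a transformed
#' scale chosen by their declared value domain: identity for real-valued,
#' natural log for strictly positive, logit for unit-interval or
#' dichotomous variables. Observations sitting exactly on a logit boundary
#' are clipped into the open interval by `eps`, half the smallest nonzero
#' distance of any observation from {0, 1}, floored at 1e-3.
#'
#' @param values observed non-missing values.
#' @param declared_domain `"real"`, `"positive"`, `"unit-interval"` or
#'   `"binary"`.
#' @return List with `name`, forward transform `fwd`, inverse `inv`, and
#'   `eps` (logit only).
#' @export
select_transform <- function(values, declared_domain) {
  values <- values[!is.na(values)]
  if (declared_domain == "positive" && any(values <= 0))
    stop("non-positive value under declared 'positive' domain")
  if (declared_domain %in% c("unit-interval", "binary") &&
      any(values < 0 | values > 1))
    stop("value outside [0,1] under declared '", declared_domain,
         "' domain")
  switch(declared_domain,
    real = list(name = "identity", fwd = identity, inv = identity),
    positive = list(name = "log", fwd = log, inv = exp),
    `unit-interval` = ,
    binary = {
      dist <- pmin(values, 1 - values)
      eps <- max(1e-3, if (any(dist > 0)) min(dist[dist > 0]) / 2 else 0)
      list(name = "logit",
           fwd = function(x) qlogis(pmin(pmax(x, eps), 1 - eps)),
           inv = plogis, eps = eps)
    },
    stop("unknown value domain: ", declared_domain))
}

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# weighted Gaussian LASSO by cyclic coordinate descent on standardized
# covariates; X already centered/scaled, y centered. Weights sum to n.
cd_lasso <- function(X, y, lambda, w = NULL, beta0 = NULL, tol = 1e-7,
                     maxit = 1e5) {
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  r <- y - drop(X %*% beta)
  xwx <- colSums(w * X^2) / n
  it <- 0
  repeat {
    delta_max <- 0
    for (j in seq_len(p)) {
      z <- beta[j] * xwx[j] + sum(w * X[, j] * r) / n
      bj <- soft_threshold(z, lambda) / xwx[j]
      d <- bj - beta[j]
      if (d != 0) {
        r <- r - X[, j] * d
        beta[j] <- bj
        delta_max <- max(delta_max, abs(d))
      }
    }
    it <- it + 1
    if (delta_max < tol) break
    if (it >= maxit)
      stop("coordinate descent failed to converge at lambda = ", lambda,
           " (max coefficient change ", signif(delta_max, 3), ")")
  }
  beta[abs(beta) < 1e-12] <- 0   # rounding dust at the KKT boundary
  beta
}

#' LASSO regularization path by cyclic coordinate descent
#'
#' Solves `min 1/(2n) sum (y - b0 - X b)^2 + lambda ||b||_1` (Gaussian) or
#' the corresponding penalized binomial log-likelihood (via iteratively
#' reweighted least squares) over a decreasing log-spaced penalty grid with
#' warm starts. Covariates are standardized to unit (population) variance
#' before penalization and coefficients are reported back on the original
#' scale; the intercept is unpenalized.
#'
#' @param X numeric covariate matrix (n x p) with column names.
#' @param y response: transformed values (Gaussian) or 0/1 (binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param lambda optional penalty grid (decreasing); default 100 log-spaced
#'   values from `lambda_max` (smallest penalty with all-zero solution)
#'   down to `1e-3 * lambda_max`.
#' @param nlambda,lambda_min_ratio grid size and lower end ratio.
#' @param tol coordinate-descent convergence tolerance on the maximum
#'   standardized-coefficient change.
#' @return List of class `lasso_path`: `lambda`, `beta` (p x nlambda,
#'   original scale), `a0` (intercepts), `df` (nonzero counts),
#'   `inclusion_order` (data frame: covariate, order, lambda at entry;
#'   grid ties broken by entry magnitude), `loglik` (in-sample),
#'   `family`, standardization constants.
#' @export
fit_lasso_path <- function(X, y, family = c("gaussian", "binomial"),
                           lambda = NULL, nlambda = 100,
                           lambda_min_ratio = 1e-3, tol = 1e-7) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  cm <- colMeans(X)
  Xc <- sweep(X, 2, cm)
  cs <- sqrt(colMeans(Xc^2))
  if (any(cs == 0)) stop("constant covariate(s): ",
                         paste(colnames(X)[cs == 0], collapse = ", "))
  Xs <- sweep(Xc, 2, cs, "/")

  if (family == "gaussian") {
    ybar <- mean(y)
    yc <- y - ybar
    lam_max <- max(abs(crossprod(Xs, yc))) / n
  } else {
    if (!all(y %in% c(0, 1))) stop("binomial response must be 0/1")
    mu0 <- mean(y)
    lam_max <- max(abs(crossprod(Xs, y - mu0))) / n
  }
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                      length.out = nlambda))
    lambda[1] <- lam_max            # guard against exp(log()) rounding
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
  }
  nl <- length(lambda)

  beta_s <- matrix(0, p, nl, dimnames = list(colnames(X), NULL))
  a0 <- numeric(nl)
  loglik <- numeric(nl)
  b <- numeric(p)
  if (family == "gaussian") {
    for (i in seq_len(nl)) {
      b <- cd_lasso(Xs, yc, lambda[i], beta0 = b, tol = tol)
      beta_s[, i] <- b
      a0[i] <- ybar
      rss <- sum((yc - Xs %*% b)^2)
      loglik[i] <- -n / 2 * (log(2 * pi * rss / n) + 1)
    }
  } else {
    for (i in seq_len(nl)) {
      b0 <- if (i == 1) qlogis(mean(y)) else a0[i - 1]
      for (irls in 1:50) {
        eta <- b0 + drop(Xs %*% b)
        mu <- plogis(eta)
        w <- pmax(mu * (1 - mu), 1e-5)
        z <- eta + (y - mu) / w
        wz <- sum(w * z) / sum(w)
        wx <- colSums(w * Xs) / sum(w)
        b_new <- cd_lasso(sweep(Xs, 2, wx), z - wz, lambda[i], w = w,
                          beta0 = b, tol = tol)
        b0_new <- wz - sum(wx * b_new)
        done <- max(abs(c(b_new - b, b0_new - b0))) < 1e-6
        b <- b_new
        b0 <- b0_new
        if (done) break
      }
      beta_s[, i] <- b
      a0[i] <- b0
      eta <- b0 + drop(Xs %*% b)
      loglik[i] <- sum(y * eta - log1p(exp(eta)))
    }
  }

  beta <- sweep(beta_s, 1, cs, "/")
  a0_orig <- a0 - colSums(beta * cm)

  first_nz <- apply(beta_s != 0, 1, function(r) {
    if (any(r)) which(r)[1] else NA_integer_
  })
  entered <- which(!is.na(first_nz))
  mag <- vapply(entered, function(j) abs(beta_s[j, first_nz[j]]), 0)
  ord <- entered[order(first_nz[entered], -mag)]
  inclusion <- data.frame(covariate = colnames(X)[ord],
                          order = seq_along(ord),
                          lambda_entry = lambda[first_nz[ord]])

  structure(list(lambda = lambda, beta = beta, a0 = a0_orig,
                 beta_std = beta_s, df = colSums(beta_s != 0),
                 inclusion_order = inclusion, loglik = loglik,
                 family = family, center = cm, scale = cs,
                 lambda_max = lam_max),
            class = "lasso_path")
}

#' Generalized coefficient of determination
#'
#' Likelihood-ratio (Cox-Snell) form
#' `R^2 = 1 - exp(-(2/n) (l_model - l_null))`. For a Gaussian model with
#' profiled variance this reduces algebraically to the classical
#' `1 - RSS_model / RSS_null`; held-out likelihoods may give negative
#' values, which are meaningful and retained.
#'
#' @param model_loglik,null_loglik log-likelihoods on the same `n`
#'   observations.
#' @param n number of observations.
#' @return The generalized R-squared (<= 1, possibly negative).
#' @export
generalized_r2 <- function(model_loglik, null_loglik, n) {
  if (n <= 0) stop("n must be positive")
  1 - exp(-(2 / n) * (model_loglik - null_loglik))
}

# held-out generalized R^2 for one fold
fold_r2 <- function(path, X_test, y_test, family, y_train) {
  n_t <- length(y_test)
  pred <- sweep(as.matrix(X_test) %*% path$beta, 2, path$a0, "+")
  if (family == "gaussian") {
    rss_m <- colSums((y_test - pred)^2)
    rss_0 <- sum((y_test - mean(y_train))^2)
    1 - rss_m / rss_0
  } else {
    ll <- function(eta) sum(y_test * eta - log1p(exp(eta)))
    ll_m <- apply(pred, 2, ll)
    p0 <- min(max(mean(y_train), 1e-10), 1 - 1e-10)
    ll_0 <- sum(y_test * qlogis(p0) - log1p(exp(qlogis(p0))))
    vapply(ll_m, generalized_r2, 0, null_loglik = ll_0, n = n_t)
  }
}

#' Cross-validated penalty selection
#'
#' Five-fold (by default) cross-validation of the LASSO path: the path is
#' refit on each training split over one shared penalty grid and scored on
#' the held-out fifth by the generalized R-squared against the
#' training-mean null model. The optimal penalty maximizes the mean CV
#' R-squared; the largest penalty whose mean lies within one standard
#' deviation of the maximum is reported alongside (the parsimony rule used
#' when bolding selected covariates).
#'
#' @param X,y covariates and transformed response (complete cases).
#' @param family `"gaussian"` or `"binomial"`.
#' @param folds number of folds (each fold needs >= 3 samples).
#' @param seed integer seed fixing the fold assignment.
#' @param ... passed to [fit_lasso_path()].
#' @return List of class `lasso_cv`: the full-data `path`, `lambda`,
#'   `cv_r2` (mean per penalty), `cv_r2_folds` (folds x penalties),
#'   `cv_sd` (s.d. of the fold values at each penalty), `lambda_opt`,
#'   `lambda_1se`, `r2_opt`, `beta_opt`, `a0_opt`, `fold_id`.
#' @export
cross_validate_penalty <- function(X, y, family = "gaussian", folds = 5,
                                   seed = 1, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  if (min(table(fold_id)) < 3) stop("a fold has fewer than 3 samples")

  path <- fit_lasso_path(X, y, family = family, ...)
  cv <- matrix(NA_real_, folds, length(path$lambda))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    pf <- fit_lasso_path(X[tr, , drop = FALSE], y[tr], family = family,
                         lambda = path$lambda, ...)
    cv[f, ] <- fold_r2(pf, X[!tr, , drop = FALSE], y[!tr], family, y[tr])
  }
  cv_mean <- colMeans(cv)
  cv_sd <- apply(cv, 2, sd)
  i_opt <- which.max(cv_mean)
  thr <- cv_mean[i_opt] - cv_sd[i_opt] / sqrt(folds)
  i_1se <- which(cv_mean >= thr)[1]
  structure(list(path = path, lambda = path$lambda, cv_r2 = cv_mean,
                 cv_r2_folds = cv, cv_sd = cv_sd,
                 lambda_opt = path$lambda[i_opt],
                 lambda_1se = path$lambda[i_1se],
                 r2_opt = cv_mean[i_opt],
                 r2_opt_sd = cv_sd[i_opt] / sqrt(folds),
                 beta_opt = path$beta[, i_opt],
                 a0_opt = path$a0[i_opt], fold_id = fold_id,
                 family = family),
            class = "lasso_cv")
}

#' Grouped variance attribution of a fitted linear predictor
#'
#' Decomposes the in-sample explained variance of a fitted model into
#' signed generalized components by covariate group: with group
#' contributions `r_.g = X_.g b_g` (centred), the share of group g is
#' `sum_h Cov(r_.g, r_.h) / Var(y)`. Shares sum exactly to the total
#' `Var(fitted) / Var(y)`; correlated groups can receive negative shares.
#'
#' @param X covariate matrix.
#' @param beta fitted coefficients (original scale), named as `X` columns.
#' @param groups named character vector mapping each covariate to a group.
#' @param y the (transformed) response the model was fitted on.
#' @return List of class `variance_attribution`: `shares` (named, one per
#'   group), `total_r2`, `residual_share`.
#' @export
attribute_variance_components <- function(X, beta, groups, y) {
  vy <- var(y)
  if (vy == 0) stop("zero-variance response")
  X <- as.matrix(X)
  glev <- unique(groups[colnames(X)])
  R <- vapply(glev, function(g) {
    j <- colnames(X)[groups[colnames(X)] == g]
    drop(X[, j, drop = FALSE] %*% beta[j])
  }, numeric(nrow(X)))
  R <- sweep(R, 2, colMeans(R))
  Sg <- cov(R)
  shares <- rowSums(Sg) / vy
  total <- var(rowSums(R)) / vy
  structure(list(shares = shares, total_r2 = total,
                 residual_share = 1 - total),
            class = "variance_attribution")
}

#' Fit a penalized phenotype model for one clinical variable
#'
#' End-to-end wrapper: builds the covariate matrix (recurrent lesions,
#' the first `n_pcs` cohort-wide expression principal components, sex and
#' age, with group labels genetic / cytogenetic / transcriptomic /
#' demographic), restricts to this phenotype's complete cases, applies the
#' range-dependent transform, cross-validates the LASSO penalty and
#' attributes the explained variance at the optimum by group.
#'
#' @param bundle a `cohort_bundle`.
#' @param phenotype name of a clinical column.
#' @param pca optional `pca_result` (recomputed if `NULL`).
#' @param n_pcs number of expression PCs to include.
#' @param min_recurrence lesion recurrence threshold.
#' @param folds,seed cross-validation controls.
#' @return List of class `phenotype_fit`: `cv` (a `lasso_cv`),
#'   `attribution`, `transform`, `n`, `covariate_groups`.
#' @export
fit_phenotype_model <- function(bundle, phenotype, pca = NULL, n_pcs = 20,
                                min_recurrence = 5, folds = 5, seed = 1) {
  if (!phenotype %in% colnames(bundle$clinical))
    stop("unknown phenotype: ", phenotype)
  if (is.null(pca))
    pca <- run_pca(bundle$expression, min(n_pcs, min(dim(
      bundle$expression)) - 1))
  n_pcs <- min(n_pcs, ncol(pca$scores))

  mask <- align_and_mask(bundle, "phenotype")[, phenotype]
  s <- bundle$samples[mask]
  if (length(s) < 20)
    stop("fewer than 20 complete cases for phenotype ", phenotype)

  les <- bundle$lesions[s, , drop = FALSE]
  les <- les[, colSums(les) >= min_recurrence, drop = FALSE]
  pcs <- pca$scores[s, seq_len(n_pcs), drop = FALSE]
  X <- cbind(les, pcs,
             sex = bundle$demographics[s, "sex"],
             age = bundle$demographics[s, "age"])
  groups <- c(setNames(unname(bundle$lesion_class[colnames(les)]),
                       colnames(les)),
              setNames(rep("transcriptomic", n_pcs), colnames(pcs)),
              sex = "demographic", age = "demographic")

  dom <- bundle$clinical_domains[[phenotype]]
  tr <- select_transform(bundle$clinical[s, phenotype], dom)
  y_raw <- bundle$clinical[s, phenotype]
  family <- if (dom == "binary") "binomial" else "gaussian"
  y <- if (family == "binomial") y_raw else tr$fwd(y_raw)

  cv <- cross_validate_penalty(X, y, family = family, folds = folds,
                               seed = seed)
  attribution <- attribute_variance_components(
    X, cv$beta_opt, groups, if (family == "binomial") y_raw else y)
  structure(list(phenotype = phenotype, cv = cv,
                 attribution = attribution, transform = tr$name,
                 n = length(s), covariate_groups = groups),
            class = "phenotype_fit")
}
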