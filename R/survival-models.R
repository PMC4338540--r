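# Breslow partial log-likelihood, gradient and Hessian for the Cox model.
# Samples sorted by increasing time; the risk set of an event includes all
# samples with time >= its time, so tied events share one risk set
# (Breslow handling). Cumulative sums from the tail give all risk-set
# aggregates in O(n p) / O(n p^2).
cox_partial <- function(X, time, status, beta, hessian = FALSE) {
  ord <- order(time)
  X <- X[ord, , drop = FALSE]
  status <- status[ord]
  ts <- time[ord]
  n <- nrow(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  shift <- max(eta)                          # overflow guard
  W <- exp(eta - shift)
  revcs <- function(x) rev(cumsum(rev(x)))
  fp <- cummax(seq_len(n) * !duplicated(ts)) # first index of each tied time
  S0 <- revcs(W)[fp]
  ev <- which(status == 1)
  if (length(ev) == 0) stop("no events in survival data")
  ll <- sum(eta[ev] - shift - log(S0[ev]))
  S1 <- apply(W * X, 2, revcs)[fp, , drop = FALSE]
  B <- S1[ev, , drop = FALSE] / S0[ev]
  grad <- colSums(X[ev, , drop = FALSE]) - colSums(B)
  out <- list(loglik = ll, grad = grad)
  if (hessian) {
    WX <- W * X
    H <- matrix(0, p, p)
    for (j in seq_len(p)) {
      S2j <- apply(WX * X[, j], 2, revcs)[fp, , drop = FALSE]
      H[j, ] <- colSums(S2j[ev, , drop = FALSE] / S0[ev])
    }
    out$hessian <- -(H - crossprod(B))       # of the log-likelihood
  }
  out
}

#' Ridge-penalized Cox proportional-hazards fit
#'
#' Maximizes the Breslow partial log-likelihood minus `(tau/2) ||beta||^2`
#' by Newton iterations with step halving, to a penalized-gradient norm of
#' `1e-8`. The single ridge precision `tau` shared by all coefficients is
#' the simplest expression of a common prior on the coefficient variances;
#' `tau = 0` gives the unpenalized maximum partial-likelihood estimate.
#'
#' @param X covariate matrix (samples x covariates), column names required.
#' @param time,status survival times (days) and 0/1 event indicators.
#' @param tau ridge precision, >= 0.
#' @param groups optional named character vector labelling each covariate
#'   with a data class (genetic, cytogenetic, transcriptomic, ...); stored
#'   for [decompose_risk_variance()].
#' @param maxit,tol Newton controls.
#' @return List of class `cox_risk_model`: `coef`, `tau`, `risk` (centred
#'   linear predictor per sample; higher = higher hazard), `loglik`
#'   (unpenalized, at the fitted coefficients), `X`, `groups`,
#'   `iterations`, `grad_norm`.
#' @export
fit_ridge_cox <- function(X, time, status, tau = 0, groups = NULL,
                          maxit = 50, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(status) < 2) stop("need at least 2 events to fit a Cox model")
  if (!all(is.finite(X))) stop("non-finite covariate values")
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))             # centring leaves PL unchanged
  beta <- numeric(p)
  if (is.infinite(tau)) {
    # exact limit: every coefficient is pinned at zero
    names(beta) <- colnames(X)
    part0 <- cox_partial(Xc, time, status, beta)
    return(structure(list(coef = beta, tau = tau,
                          risk = setNames(numeric(nrow(X)), rownames(X)),
                          loglik = part0$loglik, X = X, groups = groups,
                          iterations = 0L, grad_norm = 0),
                     class = "cox_risk_model"))
  }
  pen_ll <- function(b, part) part$loglik - tau / 2 * sum(b^2)
  part <- cox_partial(Xc, time, status, beta, hessian = TRUE)
  for (it in seq_len(maxit)) {
    g <- part$grad - tau * beta
    if (sqrt(sum(g^2)) <= tol) break
    Hp <- -part$hessian + diag(tau, p)
    step <- solve(Hp, g)
    f0 <- pen_ll(beta, part)
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * step
      part_new <- cox_partial(Xc, time, status, beta_new, hessian = TRUE)
      if (pen_ll(beta_new, part_new) >= f0 - 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- beta_new
    part <- part_new
    if (it == maxit) {
      g <- part$grad - tau * beta
      if (sqrt(sum(g^2)) > tol)
        stop("ridge Cox Newton failed to converge: |grad| = ",
             signif(sqrt(sum(g^2)), 3), " after ", maxit, " iterations")
    }
  }
  names(beta) <- colnames(X)
  risk <- drop(Xc %*% beta)
  names(risk) <- rownames(X)
  structure(list(coef = beta, tau = tau, risk = risk,
                 loglik = part$loglik, X = X, groups = groups,
                 iterations = it,
                 grad_norm = sqrt(sum((part$grad - tau * beta)^2))),
            class = "cox_risk_model")
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering
#' matches the observed survival ordering. A pair is comparable when the
#' earlier of the two times is an observed event (and the times differ);
#' it is concordant when the earlier event carries the higher risk; risk
#' ties count one half.
#'
#' @param time,status survival times and 0/1 event indicators.
#' @param risk predicted risk scores (higher = shorter survival).
#' @return C in `[0, 1]`; 0.5 is random.
#' @export
harrells_c <- function(time, status, risk) {
  stopifnot(length(time) == length(status),
            length(time) == length(risk))
  comp <- outer(time, time, "<") & (status == 1)   # row i earlier event
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs")
  conc <- sum(comp & outer(risk, risk, ">"))
  ties <- sum(comp & outer(risk, risk, "=="))
  (conc + 0.5 * ties) / n_comp
}

# Verweij-van Houwelingen cross-validated partial likelihood for one tau
cv_partial_likelihood <- function(X, time, status, tau, fold_id) {
  cvl <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    if (sum(status[tr]) < 2) next
    fit <- fit_ridge_cox(X[tr, , drop = FALSE], time[tr], status[tr],
                         tau = tau)
    b <- fit$coef
    Xc <- sweep(X, 2, colMeans(X[tr, , drop = FALSE]))
    ll_all <- cox_partial(Xc, time, status, b)$loglik
    ll_tr <- cox_partial(Xc[tr, , drop = FALSE], time[tr], status[tr],
                         b)$loglik
    cvl <- cvl + (ll_all - ll_tr)
  }
  cvl
}

#' Choose the shared ridge precision by cross-validated partial likelihood
#'
#' Evaluates each candidate precision by the Verweij-van Houwelingen
#' cross-validated partial likelihood (the difference between the full-data
#' and training-data partial log-likelihoods at the training-data fit,
#' summed over folds) and returns the maximizer. Used on training data
#' only inside [cross_validated_concordance()], keeping penalty selection
#' leakage-free.
#'
#' @param X covariate matrix.
#' @param time,status survival data.
#' @param tau_grid candidate ridge precisions (> 0).
#' @param folds,seed inner-fold controls.
#' @return The selected precision.
#' @export
select_tau <- function(X, time, status, tau_grid, folds = 5, seed = 1) {
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = nrow(X)))
  cvl <- vapply(tau_grid, function(tau)
    cv_partial_likelihood(X, time, status, tau, fold_id), 0)
  tau_grid[which.max(cvl)]
}

#' Cross-validated concordance of a covariate set
#'
#' Five-fold (by default) cross-validation: the cohort is split into folds
#' of approximately equal size; for each fold a ridge Cox model is trained
#' on the remaining folds -- with the shared ridge precision chosen by an
#' inner five-fold cross-validated partial likelihood on the training data
#' only -- and Harrell's C is evaluated on the held-out fold. The mean of
#' the per-fold C values is reported with the standard deviation of the
#' mean. Fold draws are retried (bounded) if a training fold lacks events
#' or a test fold lacks comparable pairs.
#'
#' @param X covariate matrix.
#' @param time,status survival data.
#' @param folds number of folds.
#' @param seed integer seed fixing folds and inner CV.
#' @param tau_grid candidate ridge precisions for the inner CV.
#' @param stratify_events balance events across folds (off by default).
#' @return List of class `concordance_report`: `fold_c`, `mean_c`,
#'   `sd_mean`, `tau` (per fold), `fold_id`.
#' @export
cross_validated_concordance <- function(X, time, status, folds = 5,
                                        seed = 1,
                                        tau_grid = exp(seq(log(0.25),
                                                           log(256),
                                                           length.out = 7)),
                                        stratify_events = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  for (try in 1:20) {
    if (stratify_events) {
      fold_id <- integer(n)
      for (s in unique(status))
        fold_id[status == s] <- sample(rep(seq_len(folds),
                                           length.out = sum(status == s)))
    } else {
      fold_id <- sample(rep(seq_len(folds), length.out = n))
    }
    ok <- all(vapply(seq_len(folds), function(f)
      sum(status[fold_id != f]) >= 2 && sum(status[fold_id == f]) >= 1,
      TRUE))
    if (ok) break
    if (try == 20) stop("could not draw folds with events in every part")
  }
  fold_c <- tau_used <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    tau <- select_tau(X[tr, , drop = FALSE], time[tr], status[tr],
                      tau_grid, seed = seed + f)
    fit <- fit_ridge_cox(X[tr, , drop = FALSE], time[tr], status[tr],
                         tau = tau)
    risk_test <- drop(sweep(X[!tr, , drop = FALSE], 2,
                            colMeans(X[tr, , drop = FALSE])) %*% fit$coef)
    fold_c[f] <- harrells_c(time[!tr], status[!tr], risk_test)
    tau_used[f] <- tau
  }
  structure(list(fold_c = fold_c, mean_c = mean(fold_c),
                 sd_mean = sd(fold_c) / sqrt(folds), tau = tau_used,
                 fold_id = fold_id, folds = folds),
            class = "concordance_report")
}

#' Exact group-wise decomposition of the risk variance
#'
#' The log hazard `r_i` of a fitted model splits into group contributions
#' `r_ig = X_ig b_g`. Because groups are correlated, the variance of `r`
#' cannot in general be split into positive per-group variances; instead
#' each group receives the generalized component
#' `s_g = sum_h Cov(r_.g, r_.h)`, its own variance plus its covariances
#' with every other group. These sum exactly to `Var(r)`; negative
#' components flag a group whose contribution is anti-correlated with the
#' rest.
#'
#' @param model a `cox_risk_model` fitted with `groups` labels (>= 2
#'   groups).
#' @return List of class `risk_decomposition`: `components` (named `s_g`),
#'   `shares` (`s_g / Var(r)`), `var_risk`, `risk_by_group` (centred
#'   matrix).
#' @export
decompose_risk_variance <- function(model) {
  if (is.null(model$groups))
    stop("model was fitted without group labels")
  glev <- unique(model$groups[colnames(model$X)])
  if (length(glev) < 2) stop("need at least 2 covariate groups")
  R <- vapply(glev, function(g) {
    j <- colnames(model$X)[model$groups[colnames(model$X)] == g]
    drop(model$X[, j, drop = FALSE] %*% model$coef[j])
  }, numeric(nrow(model$X)))
  R <- sweep(R, 2, colMeans(R))
  vr <- var(rowSums(R))
  if (vr == 0) stop("risk variance is zero")
  s_g <- rowSums(cov(R))
  structure(list(components = s_g, shares = s_g / vr, var_risk = vr,
                 risk_by_group = R),
            class = "risk_decomposition")
}

#' Kaplan-Meier curves for risk terciles
#'
#' Cuts the cohort at the terciles of the predicted risk and estimates the
#' product-limit survival curve per tercile, reporting whether the three
#' curves are stochastically ordered (high-risk curve at or below the
#' middle, middle at or below the low) at every shared time point.
#'
#' @param risk predicted risk per sample.
#' @param time,status survival data (>= 9 samples).
#' @param conf.int passed to [survival::survfit()].
#' @return List of class `km_terciles`: `curves` (data frame: tercile,
#'   time, n_risk, n_event, surv), `ordered` (logical), `fit` (the
#'   `survfit` object), `cuts`.
#' @export
kaplan_meier_terciles <- function(risk, time, status, conf.int = FALSE) {
  if (length(risk) < 9) stop("need at least 9 samples for terciles")
  cuts <- quantile(risk, c(1 / 3, 2 / 3))
  if (length(unique(risk)) == 1 || cuts[1] == cuts[2])
    stop("risk terciles undefined: risks (nearly) all identical")
  grp <- cut(risk, c(-Inf, cuts, Inf),
             labels = c("low", "mid", "high"))
  fit <- survival::survfit(survival::Surv(time, status) ~ grp,
                           conf.int = conf.int)
  sm <- summary(fit)
  curves <- data.frame(
    tercile = sub("^grp=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    surv = sm$surv)
  step_at <- function(terc, t) {
    cc <- curves[curves$tercile == terc, ]
    vapply(t, function(ti) {
      i <- cc$time <= ti
      if (any(i)) cc$surv[max(which(i))] else 1
    }, 0)
  }
  tt <- sort(unique(curves$time))
  ordered <- all(step_at("high", tt) <= step_at("mid", tt) + 1e-12) &&
    all(step_at("mid", tt) <= step_at("low", tt) + 1e-12)
  structure(list(curves = curves, ordered = ordered, fit = fit,
                 cuts = cuts), class = "km_terciles")
}

#' Genotype-predicted expression principal components
#'
#' Regresses each observed expression PC score on the genomic design
#' columns (intercept + genetic + cytogenetic; demographics excluded) and
#' returns the fitted scores. The predicted PCs carry only the
#' mutation-driven part of the transcriptome and can stand in for
#' expression as a survival covariate class when expression is not
#' measured.
#'
#' @param pca a `pca_result` whose score rows match the design samples.
#' @param design a `design_matrix` from [build_design_matrix()].
#' @param newdata optional lesion design matrix (same columns) for which
#'   to predict; defaults to the training design.
#' @return List of class `predicted_expression`: `scores` (samples x PCs,
#'   fitted), `coef` (design columns x PCs).
#' @export
predict_expression_from_genotype <- function(pca, design, newdata = NULL) {
  keep <- design$groups %in% c("intercept", "genetic", "cytogenetic")
  Xg <- design$X[, keep, drop = FALSE]
  S <- pca$scores[rownames(Xg), , drop = FALSE]
  fit <- lm.fit(Xg, S)
  coefs <- fit$coefficients
  if (is.null(newdata)) {
    pred <- Xg %*% coefs
  } else {
    if (!all(colnames(Xg) %in% colnames(newdata)))
      stop("newdata lacks the trained design columns: ",
           paste(setdiff(colnames(Xg), colnames(newdata)), collapse = ", "))
    pred <- as.matrix(newdata[, colnames(Xg), drop = FALSE]) %*% coefs
  }
  structure(list(scores = pred, coef = coefs),
            class = "predicted_expression")
}

# assemble one covariate block per predictor class from a bundle
survival_design_blocks <- function(bundle, n_pcs = 20, min_recurrence = 5,
                                   pca = NULL) {
  mask <- align_and_mask(bundle, "survival")
  s <- bundle$samples[mask]
  if (is.null(pca))
    pca <- run_pca(bundle$expression,
                   min(n_pcs, min(dim(bundle$expression)) - 1))
  n_pcs <- min(n_pcs, ncol(pca$scores))
  les <- bundle$lesions[s, , drop = FALSE]
  les <- les[, colSums(les) >= min_recurrence, drop = FALSE]
  cls <- bundle$lesion_class[colnames(les)]

  blood <- as.matrix(bundle$clinical[s, , drop = FALSE])
  for (v in colnames(blood)) {
    tr <- select_transform(blood[, v], bundle$clinical_domains[[v]])
    blood[, v] <- tr$fwd(blood[, v])
  }

  dm <- build_design_matrix(bundle, min_recurrence = min_recurrence)
  pe <- predict_expression_from_genotype(pca, dm)
  pe_scores <- pe$scores[s, seq_len(n_pcs), drop = FALSE]
  colnames(pe_scores) <- paste0("pred", colnames(pe_scores))

  list(samples = s,
       time = bundle$survival[s, "time"],
       status = bundle$survival[s, "status"],
       blocks = list(
         genetic = les[, cls == "genetic", drop = FALSE],
         cytogenetic = les[, cls == "cytogenetic", drop = FALSE],
         expression = pca$scores[s, seq_len(n_pcs), drop = FALSE],
         predicted_expression = pe_scores,
         blood = blood,
         demographic = cbind(sex = bundle$demographics[s, "sex"],
                             age = bundle$demographics[s, "age"])))
}

#' Compare the prognostic value of predictor classes
#'
#' Cross-validated Harrell's C for each requested covariate class
#' (genetic, cytogenetic, expression = first `n_pcs` PCs,
#' predicted_expression = genotype-predicted PCs, blood = transformed
#' clinical variables, demographic) and for their union (`"all"`), each on
#' its own complete-case sample set. `repeats` > 1 re-runs the CV with
#' fresh fold draws and pools the per-fold values.
#'
#' @param bundle a `cohort_bundle`.
#' @param classes character vector of class names; `"all"` = union of
#'   genetic, cytogenetic, expression, blood, demographic.
#' @param n_pcs,min_recurrence design controls.
#' @param folds,seed,repeats cross-validation controls.
#' @param pca optional precomputed `pca_result`.
#' @return Data frame of class `class_comparison`: one row per class with
#'   `mean_c`, `sd_mean`, `n`, `n_covariates`; per-fold values in
#'   `attr(, "reports")`.
#' @export
compare_predictor_classes <- function(bundle,
                                      classes = c("genetic", "cytogenetic",
                                                  "expression", "blood",
                                                  "demographic", "all"),
                                      n_pcs = 20, min_recurrence = 5,
                                      folds = 5, seed = 1, repeats = 1,
                                      pca = NULL) {
  sd_blocks <- survival_design_blocks(bundle, n_pcs = n_pcs,
                                      min_recurrence = min_recurrence,
                                      pca = pca)
  known <- c(names(sd_blocks$blocks), "all")
  if (!all(classes %in% known))
    stop("unknown predictor class(es): ",
         paste(setdiff(classes, known), collapse = ", "))
  reports <- list()
  rows <- list()
  for (cl in classes) {
    Xcl <- if (cl == "all") {
      do.call(cbind, sd_blocks$blocks[c("genetic", "cytogenetic",
                                        "expression", "blood",
                                        "demographic")])
    } else sd_blocks$blocks[[cl]]
    cc <- complete.cases(Xcl)
    Xcl <- Xcl[cc, , drop = FALSE]
    keep <- apply(Xcl, 2, function(x) length(unique(x)) > 1)
    Xcl <- Xcl[, keep, drop = FALSE]
    fold_c <- unlist(lapply(seq_len(repeats), function(r) {
      cross_validated_concordance(Xcl, sd_blocks$time[cc],
                                  sd_blocks$status[cc], folds = folds,
                                  seed = seed + 1000 * (r - 1))$fold_c
    }))
    reports[[cl]] <- fold_c
    rows[[cl]] <- data.frame(class = cl, mean_c = mean(fold_c),
                             sd_mean = sd(fold_c) / sqrt(length(fold_c)),
                             n = sum(cc), n_covariates = ncol(Xcl))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "reports") <- reports
  class(out) <- c("class_comparison", class(out))
  out
}
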