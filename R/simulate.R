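#' Default simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-cohort
#' generator. The defaults emulate a desk-scale myelodysplastic-syndrome
#' (MDS) cohort: ~150 CD34+ samples including a small set of healthy
#' controls, 16 recurrent driver lesions (12 gene mutations, 4 cytogenetic
#' alterations) with realistic marginal frequencies and a handful of
#' co-occurrence / mutual-exclusivity interactions, 2,000 genes with sparse
#' additive lesion effects, a low-rank latent-factor background, gene-wise
#' noise variances drawn from a scaled inverse chi-square prior, four
#' range-transformed blood/bone-marrow phenotypes, and exponential survival
#' driven by grouped covariates with independent exponential censoring.
#'
#' @param n_samples total samples (disease + controls).
#' @param n_normals healthy controls; all-zero lesion rows.
#' @param n_genes number of genes.
#' @param lesion_names,lesion_class,lesion_freq lesion spec; frequencies are
#'   marginal mutation probabilities among disease samples.
#' @param interaction symmetric lesions x lesions matrix of pairwise
#'   log-odds interactions used by the sequential conditional sampler.
#' @param targets_per_lesion number of genes with a nonzero effect per
#'   lesion.
#' @param effect_sd standard deviation of the Gaussian from which nonzero
#'   lesion effects (log2 units) are drawn; a minimum magnitude of half an
#'   `effect_sd` keeps "true target" well defined.
#' @param effect_fixed if non-`NULL`, every nonzero lesion effect has this
#'   magnitude with a random sign instead of being drawn from a Gaussian.
#' @param n_factors,loading_sd latent expression factors (scores N(0,1)) and
#'   the sd of their gene loadings.
#' @param d0_true,s0sq_true parameters of the scaled inverse chi-square from
#'   which gene noise variances are drawn (the same family the moderated
#'   statistics assume, enabling recovery tests).
#' @param disease_targets,disease_effect_sd genes shifted in disease vs
#'   normal samples, absorbed downstream by the disease indicator.
#' @param phenotypes named list; each element has `domain`, lesion
#'   coefficient vector `beta_lesions`, factor coefficients `beta_factors`,
#'   `intercept`, `noise_sd` (on the transformed scale) and `missing_rate`.
#' @param surv_coef named list of survival log-hazard coefficient vectors by
#'   group: `genetic`, `cytogenetic`, `factors`, `demographic` (sex, age).
#' @param surv_scale baseline mean survival time in days.
#' @param censor_rate target fraction of censored observations, in [0, 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 150,
                       n_normals = 15,
                       n_genes = 2000,
                       lesion_names = c("SF3B1", "TET2", "SRSF2", "ASXL1",
                                        "DNMT3A", "RUNX1", "U2AF1", "TP53",
                                        "EZH2", "IDH2", "STAG2", "ZRSR2",
                                        "del_5q", "del_7q", "tri_8",
                                        "del_20q"),
                       lesion_class = c(rep("genetic", 12),
                                        rep("cytogenetic", 4)),
                       lesion_freq = c(0.22, 0.20, 0.14, 0.12, 0.10, 0.09,
                                       0.08, 0.07, 0.06, 0.05, 0.05, 0.04,
                                       0.10, 0.07, 0.06, 0.05),
                       interaction = NULL,
                       targets_per_lesion = 50,
                       effect_sd = 0.7,
                       effect_fixed = NULL,
                       n_factors = 3,
                       loading_sd = 0.25,
                       d0_true = 4,
                       s0sq_true = 0.25,
                       disease_targets = 100,
                       disease_effect_sd = 0.5,
                       phenotypes = NULL,
                       surv_coef = NULL,
                       surv_scale = 1500,
                       censor_rate = 0.35) {
  L <- length(lesion_names)
  stopifnot(length(lesion_class) == L, length(lesion_freq) == L,
            all(lesion_freq > 0 & lesion_freq < 1),
            n_normals >= 0, n_normals < n_samples,
            censor_rate >= 0, censor_rate < 1,
            n_genes >= targets_per_lesion)
  names(lesion_class) <- names(lesion_freq) <- lesion_names

  if (is.null(interaction)) {
    interaction <- matrix(0, L, L, dimnames = list(lesion_names,
                                                   lesion_names))
    # spliceosome mutations are mutually exclusive; a few known
    # co-occurrence patterns
    set_pair <- function(a, b, v) {
      interaction[a, b] <<- v; interaction[b, a] <<- v
    }
    set_pair("SF3B1", "SRSF2", -2.5)
    set_pair("SF3B1", "U2AF1", -2.5)
    set_pair("SRSF2", "U2AF1", -2.5)
    set_pair("SRSF2", "TET2", 1.5)
    set_pair("EZH2", "del_7q", 1.5)
    set_pair("TP53", "del_5q", 1.2)
  }
  stopifnot(identical(dim(interaction), c(L, L)),
            isTRUE(all.equal(interaction, t(interaction))))

  if (is.null(phenotypes)) {
    bl <- function(...) {
      b <- setNames(numeric(L), lesion_names)
      v <- c(...)
      b[names(v)] <- v
      b
    }
    phenotypes <- list(
      haemoglobin = list(domain = "positive", intercept = log(10),
        beta_lesions = bl(SF3B1 = 0.08, del_5q = -0.10, TP53 = -0.12),
        beta_factors = c(0.10, 0, 0), noise_sd = 0.15, missing_rate = 0.05),
      platelets = list(domain = "positive", intercept = log(180),
        beta_lesions = bl(del_5q = 0.35, SRSF2 = -0.25, RUNX1 = -0.30),
        beta_factors = c(0, 0.25, 0), noise_sd = 0.45, missing_rate = 0.05),
      bm_blasts = list(domain = "unit-interval", intercept = qlogis(0.04),
        beta_lesions = bl(RUNX1 = 0.9, TP53 = 0.8, ASXL1 = 0.5,
                          del_7q = 0.6, SF3B1 = -0.5),
        beta_factors = c(0.5, 0, 0), noise_sd = 0.8, missing_rate = 0.05),
      ring_sideroblasts = list(domain = "unit-interval",
        intercept = qlogis(0.02),
        beta_lesions = bl(SF3B1 = 3.0, SRSF2 = 0.8),
        beta_factors = c(0, 0, 0.4), noise_sd = 0.9, missing_rate = 0.10))
  }

  if (is.null(surv_coef)) {
    gen <- setNames(numeric(sum(lesion_class == "genetic")),
                    lesion_names[lesion_class == "genetic"])
    gen[c("TP53", "RUNX1", "EZH2", "ASXL1", "SF3B1")] <-
      c(1.1, 0.7, 0.7, 0.5, -0.4)
    cyt <- setNames(numeric(sum(lesion_class == "cytogenetic")),
                    lesion_names[lesion_class == "cytogenetic"])
    cyt[c("del_7q", "del_5q")] <- c(0.8, 0.3)
    surv_coef <- list(genetic = gen, cytogenetic = cyt,
                      factors = c(0.45, -0.2, 0),
                      demographic = c(sex = -0.1, age = 0.025))
  }

  structure(list(
    n_samples = n_samples, n_normals = n_normals, n_genes = n_genes,
    lesion_names = lesion_names, lesion_class = lesion_class,
    lesion_freq = lesion_freq, interaction = interaction,
    targets_per_lesion = targets_per_lesion, effect_sd = effect_sd,
    effect_fixed = effect_fixed,
    n_factors = n_factors, loading_sd = loading_sd,
    d0_true = d0_true, s0sq_true = s0sq_true,
    disease_targets = disease_targets,
    disease_effect_sd = disease_effect_sd,
    phenotypes = phenotypes, surv_coef = surv_coef,
    surv_scale = surv_scale, censor_rate = censor_rate
  ), class = "sim_config")
}

# per-stage seed streams: stage toggling must not shift other stages
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Simulate a binary driver-lesion matrix
#'
#' Lesions are drawn sequentially in their configured order by conditional
#' logistic sampling: lesion j is Bernoulli with log-odds equal to its
#' marginal logit plus the interaction-weighted, frequency-centred
#' indicators of earlier lesions. With a zero interaction matrix the
#' marginals are exact; with interactions the centring keeps them correct to
#' first order while pairwise odds ratios follow the interaction signs.
#' Healthy controls get all-zero rows.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return Binary matrix samples x lesions with sample row names
#'   (`S001`...), controls last.
#' @export
simulate_mutation_matrix <- function(config, seed) {
  set.seed(derive_seed(seed, "lesions"))
  n <- config$n_samples
  n_dis <- n - config$n_normals
  L <- length(config$lesion_names)
  X <- matrix(0L, n, L,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              config$lesion_names))
  f <- config$lesion_freq
  for (j in seq_len(L)) {
    eta <- qlogis(f[j])
    if (j > 1) {
      prev <- sweep(X[seq_len(n_dis), seq_len(j - 1), drop = FALSE],
                    2, f[seq_len(j - 1)])
      eta <- eta + drop(prev %*% config$interaction[seq_len(j - 1), j])
    }
    p <- plogis(eta)
    if (any(!is.finite(p)))
      stop("infeasible lesion frequency/interaction combination")
    X[seq_len(n_dis), j] <- rbinom(n_dis, 1, p)
  }
  X
}

#' Simulate a log-scale expression matrix with known ground truth
#'
#' Expression for gene k in sample i is the sum of a gene baseline, a
#' disease-vs-normal shift on a random subset of genes, additive lesion
#' effects `(X B)_ik` for a sparse effect matrix `B`, small sex and age
#' effects, a low-rank latent-factor background, and Gaussian noise whose
#' gene-wise variances are drawn from a scaled inverse chi-square with
#' parameters `(d0_true, s0sq_true)` -- the same heteroscedastic family the
#' moderated statistics shrink towards.
#'
#' @param lesions binary matrix from [simulate_mutation_matrix()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param normal logical vector flagging control samples (default: none).
#' @param demographics optional data frame with `sex` and `age` used for
#'   small demographic expression effects; omitted if `NULL`.
#' @return List with `expression` (genes x samples) and `truth`, a list
#'   holding the effect matrix `B` (lesions x genes), target-gene indices
#'   per lesion, factor scores/loadings and realized noise variances.
#' @export
simulate_expression <- function(lesions, config, seed, normal = NULL,
                                demographics = NULL) {
  set.seed(derive_seed(seed, "expression"))
  n <- nrow(lesions)
  G <- config$n_genes
  if (G < config$targets_per_lesion)
    stop("n_genes smaller than requested targets per lesion")
  genes <- sprintf("G%04d", seq_len(G))
  if (is.null(normal)) normal <- rep(FALSE, n)

  baseline <- rnorm(G, mean = 8, sd = 1.5)
  sigma2 <- config$d0_true * config$s0sq_true / rchisq(G, config$d0_true)

  B <- matrix(0, ncol(lesions), G,
              dimnames = list(colnames(lesions), genes))
  targets <- list()
  for (j in seq_len(ncol(lesions))) {
    if (config$targets_per_lesion == 0) {
      targets[[colnames(lesions)[j]]] <- integer(0)
      next
    }
    idx <- sample.int(G, config$targets_per_lesion)
    if (is.null(config$effect_fixed)) {
      eff <- rnorm(config$targets_per_lesion, 0, config$effect_sd)
      # enforce a minimum magnitude so "true target" is unambiguous
      eff <- sign(eff) * pmax(abs(eff), config$effect_sd / 2)
    } else {
      eff <- sample(c(-1, 1), config$targets_per_lesion,
                    replace = TRUE) * config$effect_fixed
    }
    B[j, idx] <- eff
    targets[[colnames(lesions)[j]]] <- sort(idx)
  }

  disease_beta <- numeric(G)
  if (config$disease_targets > 0) {
    di <- sample.int(G, min(config$disease_targets, G))
    disease_beta[di] <- rnorm(length(di), 0, config$disease_effect_sd)
  }

  sex_beta <- age_beta <- numeric(G)
  if (!is.null(demographics)) {
    sex_beta[sample.int(G, 20)] <- rnorm(20, 0, 0.3)
    age_beta[sample.int(G, 20)] <- rnorm(20, 0, 0.01)
  }

  scores <- matrix(rnorm(n * config$n_factors), n, config$n_factors)
  loadings <- matrix(rnorm(G * config$n_factors, 0, config$loading_sd),
                     G, config$n_factors)

  Y <- matrix(baseline, G, n) +
    outer(disease_beta, as.numeric(!normal)) +
    t(lesions %*% B) +
    loadings %*% t(scores) +
    matrix(rnorm(G * n, 0, sqrt(sigma2)), G, n)
  if (!is.null(demographics))
    Y <- Y + outer(sex_beta, demographics$sex) +
      outer(age_beta, demographics$age - mean(demographics$age))
  dimnames(Y) <- list(genes, rownames(lesions))

  list(expression = Y,
       truth = list(B = B, targets = targets, disease_beta = disease_beta,
                    factor_scores = scores, factor_loadings = loadings,
                    noise_var = sigma2, baseline = baseline))
}

sim_transform <- function(domain) {
  switch(domain,
         real = list(fwd = identity, inv = identity),
         positive = list(fwd = log, inv = exp),
         `unit-interval` = list(fwd = qlogis, inv = plogis),
         binary = list(fwd = qlogis, inv = plogis),
         stop("unknown transform/domain name: ", domain))
}

#' Simulate range-transformed clinical phenotypes
#'
#' For each configured phenotype the linear predictor over lesions and
#' latent factors gets Gaussian noise on the transformed scale, the declared
#' transform is inverted (identity for real, exp for positive, inverse-logit
#' for unit-interval/binary), and values are masked missing completely at
#' random at the configured rate.
#'
#' @param lesions binary lesion matrix (samples x lesions).
#' @param factors latent factor scores (samples x k) from
#'   [simulate_expression()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List with `clinical` (data frame, `NA` = missing), `domains`
#'   (named character) and `truth` (per-phenotype coefficients used).
#' @export
simulate_phenotypes <- function(lesions, factors, config, seed) {
  set.seed(derive_seed(seed, "phenotypes"))
  n <- nrow(lesions)
  out <- list()
  domains <- character(0)
  truth <- list()
  for (nm in names(config$phenotypes)) {
    ph <- config$phenotypes[[nm]]
    tr <- sim_transform(ph$domain)
    eta <- ph$intercept + drop(lesions %*% ph$beta_lesions) +
      drop(factors %*% ph$beta_factors[seq_len(ncol(factors))]) +
      rnorm(n, 0, ph$noise_sd)
    val <- tr$inv(eta)
    miss <- runif(n) < ph$missing_rate
    val[miss] <- NA
    out[[nm]] <- val
    domains[nm] <- ph$domain
    truth[[nm]] <- ph
  }
  clinical <- as.data.frame(out, row.names = rownames(lesions))
  list(clinical = clinical, domains = domains, truth = truth)
}

#' Simulate right-censored survival from grouped covariates
#'
#' Event times are exponential with rate `exp(r_i) / scale`, where the log
#' hazard `r_i` sums group-wise linear predictors (genetic and cytogenetic
#' lesions, latent expression factors, demographics). Censoring is an
#' independent exponential whose rate is tuned numerically so the expected
#' censored fraction matches the configured target.
#'
#' @param groups named list of numeric design matrices (samples x covariates
#'   per group) matching `config$surv_coef`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List with `survival` (data frame `time`, `status`), `risk` (the
#'   true log hazard, centred) and `risk_by_group` (matrix of group
#'   contributions).
#' @export
simulate_survival <- function(groups, config, seed) {
  set.seed(derive_seed(seed, "survival"))
  if (config$surv_scale <= 0) stop("baseline survival scale must be > 0")
  coefs <- config$surv_coef
  stopifnot(all(names(coefs) %in% c(names(groups))))
  n <- nrow(groups[[1]])
  rg <- vapply(names(coefs), function(g) {
    M <- as.matrix(groups[[g]])
    b <- coefs[[g]][seq_len(min(length(coefs[[g]]), ncol(M)))]
    if (length(b) == 0) return(numeric(n))
    drop(M[, seq_along(b), drop = FALSE] %*% b)
  }, numeric(n))
  rg <- sweep(rg, 2, colMeans(rg))
  r <- rowSums(rg)
  rate <- exp(r) / config$surv_scale
  t_event <- rexp(n, rate)
  if (config$censor_rate > 0) {
    f <- function(logc) mean(exp(logc) / (exp(logc) + rate)) -
      config$censor_rate
    logc <- uniroot(f, lower = log(min(rate)) - 20,
                    upper = log(max(rate)) + 20)$root
    t_cens <- rexp(n, exp(logc))
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  status <- as.integer(t_event <= t_cens)
  surv <- data.frame(time = time, status = status,
                     row.names = rownames(groups[[1]]))
  list(survival = surv, risk = r, risk_by_group = rg)
}

#' Simulate a complete cohort with ground truth
#'
#' Composes [simulate_mutation_matrix()], [simulate_expression()],
#' [simulate_phenotypes()] and [simulate_survival()] into an aligned
#' [cohort_bundle()], carrying every generative parameter in the returned
#' `truth` so downstream recovery tests can compare against it. All
#' randomness is a pure function of `(config, seed)`; each component draws
#' from an independent per-stage stream.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List with `bundle` (a `cohort_bundle`) and `truth`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  set.seed(derive_seed(seed, "demographics"))
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  normal <- c(rep(FALSE, n - config$n_normals),
              rep(TRUE, config$n_normals))
  names(normal) <- ids
  demo <- data.frame(sex = rbinom(n, 1, 0.45),
                     age = as.integer(round(pmin(pmax(
                       rnorm(n, 68, 10), 25), 95))),
                     row.names = ids)

  X <- simulate_mutation_matrix(config, seed)
  ex <- simulate_expression(X, config, seed, normal = normal,
                            demographics = demo)
  ph <- simulate_phenotypes(X, ex$truth$factor_scores, config, seed)
  groups <- list(
    genetic = X[, config$lesion_class == "genetic", drop = FALSE],
    cytogenetic = X[, config$lesion_class == "cytogenetic", drop = FALSE],
    factors = ex$truth$factor_scores,
    demographic = cbind(sex = demo$sex, age = demo$age - mean(demo$age)))
  sv <- simulate_survival(groups, config, seed)
  sv$survival$time[normal] <- NA
  sv$survival$status[normal] <- 0L

  bundle <- cohort_bundle(ex$expression, X, config$lesion_class,
                          ph$clinical, ph$domains, demo, sv$survival,
                          normal)
  truth <- c(ex$truth,
             list(phenotypes = ph$truth, surv_coef = config$surv_coef,
                  risk = sv$risk, risk_by_group = sv$risk_by_group,
                  config = config, seed = seed))
  list(bundle = bundle, truth = truth)
}
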