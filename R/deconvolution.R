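#' Principal components of the transcriptome
#'
#' PCA of the gene-centred expression matrix over samples, with a
#' deterministic sign convention (the largest-magnitude gene loading of
#' each component is made positive) so repeated runs are bit-identical.
#'
#' @param expr numeric matrix, genes x samples, no missing values.
#' @param k number of components to return; `k <= min(genes, samples)`.
#' @return List of class `pca_result`: `scores` (samples x k), `loadings`
#'   (genes x k), `var_frac` (variance fraction of every component, summing
#'   to 1 over the full rank).
#' @export
run_pca <- function(expr, k) {
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (k < 1 || k > min(dim(expr)))
    stop("k must be between 1 and min(genes, samples)")
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  var_frac <- var_all / sum(var_all)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 var_frac = var_frac), class = "pca_result")
}

#' Build the per-gene regression design matrix
#'
#' Columns: intercept, disease-vs-normal indicator (captures changes common
#' to all disease samples; dropped with a warning when no controls are in
#' the bundle), one 0/1 column per recurrent lesion, sex (1 = female) and
#' age in years. Lesions carried by fewer than `min_recurrence` masked
#' samples are excluded. Each column carries a group label used downstream:
#' `intercept`, `disease`, `genetic`, `cytogenetic`, `demographic`.
#'
#' @param bundle a `cohort_bundle`.
#' @param min_recurrence minimum number of carriers for a lesion to enter.
#' @param mask logical sample mask (default: the deconvolution mask from
#'   [align_and_mask()]).
#' @return List of class `design_matrix`: `X` (samples x columns), `groups`
#'   (named character per column), `samples`.
#' @export
build_design_matrix <- function(bundle, min_recurrence = 5, mask = NULL) {
  if (is.null(mask)) mask <- align_and_mask(bundle, "deconvolution")
  s <- bundle$samples[mask]
  les <- bundle$lesions[s, , drop = FALSE]
  keep <- colSums(les) >= min_recurrence
  les <- les[, keep, drop = FALSE]

  disease <- as.numeric(!bundle$normal[s])
  cols <- list(`(Intercept)` = rep(1, length(s)))
  groups <- c(`(Intercept)` = "intercept")
  if (length(unique(disease)) > 1) {
    cols$disease <- disease
    groups["disease"] <- "disease"
  } else {
    warning("disease indicator is constant (no controls); dropped")
  }
  for (l in colnames(les)) {
    cols[[l]] <- les[, l]
    groups[l] <- unname(bundle$lesion_class[l])
  }
  cols$sex <- bundle$demographics[s, "sex"]
  cols$age <- bundle$demographics[s, "age"]
  groups[c("sex", "age")] <- "demographic"

  X <- do.call(cbind, cols)
  rownames(X) <- s
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, groups = groups, samples = s),
            class = "design_matrix")
}

#' Fit per-gene linear expression models
#'
#' One least-squares fit per gene, `Y_k = X beta_k + eps_k`, via a single
#' shared QR factorization of the design. The residual degrees of freedom
#' are `n - rank(X)` for every gene. Also fits the reduced design without
#' the genomic (genetic + cytogenetic) block, whose residual sums of
#' squares feed the moderated F-test and the genomic R-squared.
#'
#' @param expr genes x samples expression matrix (must cover the design's
#'   samples).
#' @param design a `design_matrix` from [build_design_matrix()].
#' @return List of class `gene_fits`: coefficient matrix (genes x p),
#'   `sigma2` (residual variances), `df`, `se_unscaled` (per-column
#'   `sqrt((X'X)^-1_jj)`), `rss_full`, `rss_reduced`, `tss`, `design`.
#' @export
fit_gene_models <- function(expr, design) {
  X <- design$X
  if (!all(rownames(X) %in% colnames(expr)))
    stop("expression matrix does not cover the design's samples")
  Y <- t(expr[, rownames(X), drop = FALSE])   # samples x genes
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("fewer samples than design columns")

  fit <- lm.fit(X, Y)
  as_mat <- function(v) if (is.null(dim(v)))
    matrix(v, ncol = ncol(Y), dimnames = list(names(v), colnames(Y)))
  else v
  coefs <- t(as_mat(fit$coefficients))         # genes x p
  rss_full <- colSums(as_mat(fit$residuals)^2)
  df <- n - fit$rank
  sigma2 <- rss_full / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se_unscaled <- sqrt(diag(XtX_inv))
  names(se_unscaled) <- colnames(X)

  genomic <- design$groups %in% c("genetic", "cytogenetic")
  if (any(genomic)) {
    fit_red <- lm.fit(X[, !genomic, drop = FALSE], Y)
    rss_reduced <- colSums(as_mat(fit_red$residuals)^2)
  } else {
    rss_reduced <- rss_full
  }
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)

  structure(list(coef = coefs, sigma2 = sigma2, df = df,
                 se_unscaled = se_unscaled, rss_full = rss_full,
                 rss_reduced = rss_reduced, tss = tss, n = n,
                 rank = fit$rank, design = design,
                 genes = colnames(Y)),
            class = "gene_fits")
}

# Newton inversion of the trigamma function (for the moment estimator of
# the prior degrees of freedom)
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-6 & y > 0
  hi <- y > 1e7
  out[lo] <- 1 / y[lo]
  out[hi] <- 1 / sqrt(y[hi])
  mid <- !lo & !hi & is.finite(y) & y > 0
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderation of per-gene variances and statistics
#'
#' Assumes gene residual variances are exchangeable draws from a scaled
#' inverse chi-square prior with `d0` degrees of freedom and scale `s0_sq`,
#' estimated in closed form by matching the mean and variance of the log
#' sample variances to the log of that prior (the classical moment
#' estimator for this hierarchy). The posterior variance
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)` replaces `s^2` in every
#' t-statistic (gaining `d0` degrees of freedom) and in the block F-test
#' over the genomic (genetic + cytogenetic) columns.
#'
#' @param fits a `gene_fits` object.
#' @return List of class `moderation` with the prior (`d0`, `s0_sq`),
#'   posterior variances `s_tilde_sq`, total degrees of freedom `df_total`,
#'   matrices `t`, `p_t` (genes x coefficients) and vectors `F`, `p_F` for
#'   the genomic block.
#' @export
moderate_statistics <- function(fits) {
  s2 <- fits$sigma2
  d <- fits$df
  if (length(s2) < 2) stop("need at least 2 genes to estimate the prior")
  pos <- s2 > 0
  if (!any(pos)) stop("all gene residual variances are zero")
  if (!all(pos))
    warning(sum(!pos), " genes with zero residual variance excluded from ",
            "prior estimation")
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  s_tilde_sq <- if (is.finite(d0)) {
    (d0 * s0_sq + d * s2) / (d0 + d)
  } else rep(s0_sq, length(s2))
  df_total <- if (is.finite(d0)) d0 + d else Inf

  se <- outer(rep(1, nrow(fits$coef)), fits$se_unscaled) *
    sqrt(s_tilde_sq)
  tstat <- fits$coef / se
  p_t <- 2 * pt(-abs(tstat), df = df_total)

  genomic <- fits$design$groups %in% c("genetic", "cytogenetic")
  q_gen <- sum(genomic)
  if (q_gen > 0) {
    Fstat <- (fits$rss_reduced - fits$rss_full) / q_gen / s_tilde_sq
    p_F <- pf(Fstat, q_gen, df_total, lower.tail = FALSE)
  } else {
    Fstat <- p_F <- rep(NA_real_, length(s2))
  }

  structure(list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde_sq,
                 df_total = df_total, t = tstat, p_t = p_t,
                 F = Fstat, p_F = p_F, q_genomic = q_gen),
            class = "moderation")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; q-values are capped at 1 and monotone in
#' p-value rank.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (`NA` passed
#'   through).
#' @return Adjusted q-values.
#' @export
adjust_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Assemble the per-gene fit table
#'
#' Combines coefficients, moderated statistics, BH q-values and
#' explained-variance fractions into one object; the work-horse container
#' for target-set extraction and reporting.
#'
#' @param fits a `gene_fits`.
#' @param mod a `moderation` (default: computed from `fits`).
#' @return List of class `gene_fit_table`: matrices `coef`, `se`, `t`,
#'   `p`, `q` (genes x coefficients), vectors `F`, `p_F`, `q_F`,
#'   `r2_genomic`, `r2_full`, plus the `moderation` prior and design
#'   groups.
#' @export
gene_fit_table <- function(fits, mod = moderate_statistics(fits)) {
  q <- apply(mod$p_t, 2, adjust_fdr)
  se <- outer(sqrt(mod$s_tilde_sq), fits$se_unscaled)
  dimnames(se) <- dimnames(fits$coef)
  r2 <- per_gene_variance_explained(fits)
  structure(list(genes = fits$genes, coef = fits$coef, se = se,
                 t = mod$t, p = mod$p_t, q = q,
                 F = mod$F, p_F = mod$p_F, q_F = adjust_fdr(mod$p_F),
                 r2_genomic = r2$r2_genomic, r2_full = r2$r2_full,
                 moderation = mod, groups = fits$design$groups),
            class = "gene_fit_table")
}

#' Per-gene variance explained by the genomic block
#'
#' Partial R-squared of the genetic + cytogenetic columns:
#' `(RSS_reduced - RSS_full) / TSS`, where the reduced model keeps
#' intercept, disease indicator, sex and age. The full-model R-squared
#' `1 - RSS_full / TSS` is returned alongside. Constant genes (zero TSS)
#' get R-squared 0 with a warning.
#'
#' @param fits a `gene_fits`.
#' @return List with `r2_genomic` and `r2_full`, both clipped to `[0, 1]`.
#' @export
per_gene_variance_explained <- function(fits) {
  tss <- fits$tss
  zero <- tss == 0
  if (any(zero)) {
    warning(sum(zero), " constant genes: R-squared set to 0")
    tss[zero] <- 1
  }
  r2g <- pmin(pmax((fits$rss_reduced - fits$rss_full) / tss, 0), 1)
  r2f <- pmin(pmax(1 - fits$rss_full / tss, 0), 1)
  r2g[zero] <- r2f[zero] <- 0
  names(r2g) <- names(r2f) <- fits$genes
  list(r2_genomic = r2g, r2_full = r2f)
}

#' Extract per-lesion target gene sets
#'
#' For every genomic design column (and the disease indicator, giving the
#' "disease-without-driver" set), the genes whose moderated-t q-value falls
#' below `fdr`, with their signed log fold change.
#'
#' @param gft a `gene_fit_table`.
#' @param fdr FDR threshold (default 0.05); `fdr = 0` gives empty sets.
#' @return Named list of data frames (`gene`, `lfc`, `q`), one per column,
#'   ordered by increasing q.
#' @export
extract_target_sets <- function(gft, fdr = 0.05) {
  cols <- names(gft$groups)[gft$groups %in%
                              c("genetic", "cytogenetic", "disease")]
  out <- list()
  for (cl in cols) {
    hit <- which(!is.na(gft$q[, cl]) & gft$q[, cl] < fdr)
    out[[cl]] <- data.frame(gene = gft$genes[hit],
                            lfc = gft$coef[hit, cl],
                            q = gft$q[hit, cl],
                            row.names = NULL)[order(gft$q[hit, cl]), ,
                                              drop = FALSE]
  }
  out
}

#' Permutation calibration of the discovery pipeline
#'
#' Verifies test calibration by permuting the genotype columns across
#' samples -- breaking all genotype-expression correlations -- and
#' re-running the full moderated-statistics pipeline each time, recording
#' how many FDR < `fdr` discoveries survive. By default each lesion column
#' is permuted independently; `scheme = "joint"` permutes the lesion block
#' with one shared permutation, preserving co-mutation structure.
#'
#' @param expr genes x samples expression matrix.
#' @param design a `design_matrix`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param fdr discovery threshold.
#' @param scheme `"per_column"` (default), `"joint"`, or `"identity"` (no
#'   shuffling; reproduces the observed counts, a degenerate check).
#' @return Data frame with one row per permutation: t-based discovery count
#'   over genomic columns, F-based count, and per-run false-discovery
#'   proportion (all discoveries are false under permutation).
#' @export
permutation_null_check <- function(expr, design, n_perm, seed, fdr = 0.05,
                                   scheme = c("per_column", "joint",
                                              "identity")) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  scheme <- match.arg(scheme)
  set.seed(seed)
  genomic <- which(design$groups %in% c("genetic", "cytogenetic"))
  n <- nrow(design$X)
  res <- data.frame(perm = seq_len(n_perm), n_disc_t = NA_integer_,
                    n_disc_F = NA_integer_)
  for (b in seq_len(n_perm)) {
    Xp <- design$X
    if (scheme == "per_column") {
      for (j in genomic) Xp[, j] <- Xp[sample.int(n), j]
    } else if (scheme == "joint") {
      Xp[, genomic] <- Xp[sample.int(n), genomic]
    }
    dp <- design
    dp$X <- Xp
    fits <- fit_gene_models(expr, dp)
    gft <- gene_fit_table(fits)
    qg <- gft$q[, names(design$groups)[genomic], drop = FALSE]
    res$n_disc_t[b] <- sum(qg < fdr, na.rm = TRUE)
    res$n_disc_F[b] <- sum(gft$q_F < fdr, na.rm = TRUE)
  }
  # under permutation every discovery is false: the per-run false-discovery
  # proportion is 1 whenever the family rejects at all. The F-family (one
  # BH family of genes) is the calibrated discovery gate; the per-column t
  # counts are the union of 16 separately controlled families.
  res$any_disc_t <- as.integer(res$n_disc_t > 0)
  res$any_disc_F <- as.integer(res$n_disc_F > 0)
  res
}
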