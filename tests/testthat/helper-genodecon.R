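# shared fixture builders and independent oracles

# small, fast cohort for structural tests
tiny_config <- function(...) {
  args <- list(n_samples = 60, n_normals = 6, n_genes = 120,
               targets_per_lesion = 10)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

tiny_bundle <- function(seed = 1, ...) {
  simulate_cohort(tiny_config(...), seed = seed)$bundle
}

# direct BH step-up computation, independent of p.adjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# O(n^2) double-loop concordance oracle: a pair is comparable when the
# earlier time is an observed event and the times differ; concordant when
# the earlier event has the higher risk; risk ties count one half
brute_force_c <- function(time, status, risk) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && status[i] == 1) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# random censored survival instance, with ties in times and risks
rand_surv_instance <- function(n, seed) {
  set.seed(seed)
  list(time = sample(1:8, n, replace = TRUE),
       status = rbinom(n, 1, 0.7),
       risk = sample(seq(-1, 1, by = 0.5), n, replace = TRUE))
}

# KKT subgradient residual for the lasso objective
# 1/(2n) ||y - Xb||^2 + lambda ||b||_1 (standardized scale)
kkt_violation <- function(X, y, beta, lambda) {
  n <- nrow(X)
  g <- crossprod(X, y - X %*% beta) / n
  v_zero <- if (any(beta == 0)) max(abs(g[beta == 0])) - lambda else -Inf
  v_nz <- if (any(beta != 0))
    max(abs(g[beta != 0] - lambda * sign(beta[beta != 0]))) else 0
  max(v_zero, v_nz)
}
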