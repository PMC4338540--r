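---
title: "Methods: deconvolving driver-lesion effects on expression, blood counts and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolving driver-lesion effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

genodecon models how recurrent driver lesions — somatic point mutations
and cytogenetic alterations coded as 0/1 covariates — propagate through a
cancer cohort's transcriptome, blood counts and survival. This vignette
documents the statistical models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic-cohort generator
does and does not emulate.

## Cohort data model

A `cohort_bundle` aligns five tables on one sorted sample list: a
log-scale expression matrix (genes × samples), a binary lesion matrix with
each lesion labelled `genetic` or `cytogenetic`, a clinical table whose
columns carry declared value domains (`real`, `positive`,
`unit-interval`, `binary`), demographics (sex, age in integer years), and
right-censored survival in days. Missing clinical values are `NA` and are
**never imputed**: every model works on its own complete cases
(`align_and_mask()` is per-analysis, and per-phenotype for clinical
models). Sample alignment uses the sorted intersection of per-table IDs so
that bundles are identical regardless of input row order. Healthy controls
must carry all-zero lesion rows; they participate in PCA and in the
expression models through a disease-vs-normal indicator, but not in
phenotype or survival fits.

## Expression deconvolution

Each gene is modelled as an additive linear function of the design —
intercept, disease indicator, one column per lesion recurrent in at least
`min_recurrence = 5` samples, sex, age:

$$Y_{ik} = \beta_{0k} + \sum_j X_{ij}\,\beta_{jk} + \varepsilon_{ik},
\qquad \varepsilon_{ik} \sim N(0, \sigma_k^2).$$

Additivity is an assumption, not a finding: a double-mutant's predicted
expression is the baseline plus the two single-lesion effects. The design
is fitted once by QR and shared across all genes; samples missing sex or
age are dropped from fits.

**Moderation.** Residual variances are assumed exchangeable across genes,
$\sigma_k^2 \sim s_0^2\,d_0/\chi^2_{d_0}$ (scaled inverse chi-square).
$(d_0, s_0^2)$ are estimated by matching the mean and variance of
$\log s_k^2$ to that prior's log-scale moments; the variance equation is
inverted through the trigamma function by Newton iteration. When the
observed spread of log variances falls below its chi-square floor the
estimator returns $d_0 = \infty$ and every posterior variance equals
$s_0^2$. Otherwise the posterior variance
$\tilde s_k^2 = (d_0 s_0^2 + d_k s_k^2)/(d_0 + d_k)$ replaces $s_k^2$ in
every t statistic (with $d_0 + d_k$ degrees of freedom) and in the block
F statistic over the genomic (genetic + cytogenetic) columns. The F test
spans only the genomic block because it gates "genes associated with at
least one driver"; disease, sex and age are tested by their own t
statistics. The test suite cross-checks the whole moderation path against
an independent empirical-Bayes implementation to 10 decimal places.

**FDR and calibration.** Benjamini–Hochberg adjustment is applied per
test family: one family per design column for the t tests, one family
over genes for the F test. `permutation_null_check()` re-runs the entire
pipeline with genotype columns permuted across samples (independently per
column by default, matching the assumption that each covariate's
association is broken separately; a `joint` scheme preserving co-mutation
structure and an `identity` degenerate check are available). A
calibration caveat worth stating explicitly: each per-lesion t family
controls its own FDR at 5%, so the *union* of 16 families sees at least
one false discovery in roughly $1 - 0.95^{16} \approx 56\%$ of null
cohorts. The calibrated "discovery count" for a whole-cohort statement is
therefore the moderated-F family, and that is what the calibration
experiments assert; both counts are reported.

**Explained variance.** The genomic R² per gene is the partial form
$(\mathrm{RSS}_{\text{reduced}} - \mathrm{RSS}_{\text{full}})/\mathrm{TSS}$,
where the reduced model keeps intercept, disease, sex and age. The
full-model R² is reported alongside. Constant genes get R² = 0 with a
warning.

## Co-mutation structure

Pairwise lesion odds ratios use the Haldane–Anscombe half-count
correction so zero cells in small cohorts stay finite. Target-set overlap
is the Jaccard index — a deliberate, documented choice; a hypergeometric
enrichment p-value against the tested gene universe is emitted alongside
for robustness. The summary statistic is the Spearman rank correlation
between log odds ratio and overlap across pairs, with a permutation
p-value obtained by relabelling pairs. Fewer than three lesions leave the
correlation undefined and raise an error rather than returning `NA`.

## Blood-count models

Each phenotype is transformed according to its declared range — identity
for real, log for positive, logit for unit-interval or dichotomous
values. Observations sitting exactly on a logit boundary are clipped into
the open interval by half the smallest nonzero distance of any
observation from {0, 1}, floored at $10^{-3}$.

The transformed response is regressed on recurrent lesions, the first
`n_pcs = 20` cohort-wide expression principal components, sex and age.
The PCs are computed once on the full cohort (not per fold): they are
unsupervised summaries of the transcriptome, and the fold-wise refit
option would change the covariate meaning across folds. Covariates are
standardized to unit population variance; the intercept is unpenalized;
coefficients are reported on the original scale.

**LASSO path.** Cyclic coordinate descent over 100 log-spaced penalties
from $\lambda_{\max} = \max_j |x_j^\top y|/n$ (the smallest penalty with
an all-zero solution) down to $10^{-3}\lambda_{\max}$, warm-started along
the path, converged when the largest standardized-coefficient change
falls below $10^{-7}$; coefficients below $10^{-12}$ are snapped to zero
so KKT boundary cases are exact. Dichotomous responses use a true
binomial likelihood via iteratively reweighted least squares around the
same Gaussian core. Inclusion order records the first grid point at which
each covariate enters; grid ties break by entry magnitude. The tests
verify the path against the soft-threshold closed form on orthonormal
designs and against an independent convex solver on general problems.

**Generalized R².** The likelihood-ratio (Cox–Snell) form
$R^2 = 1 - \exp\{-(2/n)(\ell_{\text{model}} - \ell_{\text{null}})\}$,
which for Gaussian fits with profiled variance reduces algebraically to
the classical $1 - \mathrm{RSS}_m/\mathrm{RSS}_0$. This definition is
isolated in one function (`generalized_r2()`) precisely because other
conventions (deviance ratio, Nagelkerke rescaling) exist; swapping it
changes one place. Held-out folds score against the training-mean null
model, so pure-noise responses give non-positive CV R² up to Monte-Carlo
error — negative values are meaningful and retained. The optimal penalty
maximizes the five-fold mean CV R²; the largest penalty within one
standard deviation of that maximum is reported for parsimony-style
selection.

**Variance attribution.** At the optimum, the linear predictor is split
by covariate group (genetic, cytogenetic, transcriptomic, demographic)
and group g receives the signed generalized share
$\sum_h \mathrm{Cov}(r_{\cdot g}, r_{\cdot h}) / \mathrm{Var}(y)$. Shares
sum exactly to the total explained-variance ratio; correlated groups can
receive negative shares, which is a feature (it flags redundancy), not a
bug.

## Survival models

The Cox proportional-hazards partial likelihood with Breslow tie handling
is penalized by $(\tau/2)\lVert\beta\rVert^2$ — a single ridge precision
shared by all coefficients, the simplest expression of a common prior on
coefficient variances. Newton iterations with step halving run to a
penalized-gradient norm of $10^{-8}$; the penalized objective is
non-decreasing by construction. All risk-set aggregates come from
tail-cumulative sums over time-sorted samples, $O(np)$ for the gradient
and $O(np^2)$ for the Hessian, with tied times sharing one risk set. At
$\tau = 0$ the fit reproduces the unpenalized maximum partial-likelihood
estimate (cross-checked against an independent implementation to
$10^{-6}$); $\tau = \infty$ is handled analytically with all coefficients
pinned at zero — the honest limit statement, since at any finite $\tau$
shrinkage rescales but does not reorder risks, so the concordance of a
shrunken model does not tend to ½.

**Concordance.** Harrell's C counts pairs in which the earlier of two
different times is an observed event; concordant means the earlier event
carries the higher predicted risk; risk ties count ½. The implementation
is vectorized and matches an $O(n^2)$ brute-force double loop exactly,
including ties and censoring. Cross-validation splits the cohort into
five parts; each training fit selects $\tau$ by an inner five-fold
Verweij–van Houwelingen cross-validated partial likelihood on training
data only (no leakage), and the held-out C values are averaged, reported
with the standard deviation of the mean. Folds are drawn without event
stratification by default (a stratified option exists); event-free folds
trigger bounded re-draws.

**Risk decomposition.** The fitted log hazard splits by covariate class,
and class g receives $s_g = \sum_h \mathrm{Cov}(r_{\cdot g},
r_{\cdot h})$, its own variance plus its covariances with the other
classes. The components sum to $\mathrm{Var}(r)$ exactly (asserted to
$10^{-10}$ on every fitted model in the tests) and reduce to plain
variances when classes are uncorrelated.

**Genotype-predicted expression.** Observed expression PC scores are
regressed on the genomic design (intercept + lesions, demographics
excluded), and the fitted scores serve as a covariate class. They carry
only the mutation-driven part of the transcriptome, which is exactly what
makes them usable for cohorts without expression data — and they encode
the expression-supervised weighting of many lesions in few covariates,
which a survival model with one coefficient per lesion must otherwise
estimate from censored outcomes alone.

## The synthetic-cohort generator

The generator is the package's test bed: it emulates the statistical
structure the models assume, with every generative parameter retained for
recovery tests.

* **Lesions.** 16 drivers (12 genetic, 4 cytogenetic) with marginal
  frequencies from 0.22 down to 0.04, the range typical of recurrent MDS
  drivers, sampled sequentially by conditional logistic draws: lesion j's
  log-odds are its marginal logit plus interaction-weighted,
  frequency-centred indicators of earlier lesions. Defaults encode
  spliceosome mutual exclusivity (*SF3B1*/*SRSF2*/*U2AF1* at log-odds
  −2.5) and a few co-occurrences (*SRSF2*–*TET2*, *EZH2*–del(7q),
  *TP53*–del(5q)). With zero interactions the marginals are exact; with
  interactions the centring keeps them correct to first order while the
  pairwise odds ratios follow the interaction signs. An exact joint
  (Ising-type) sampler was deliberately not attempted — sign and
  approximate magnitude control suffice for testing the structure
  statistics.
* **Expression.** 2,000 genes by default (configurable upward): baseline
  ~N(8, 1.5²) log₂ units, 50 targets per lesion with Gaussian effects
  (sd 0.7, minimum magnitude half an sd so "true target" is unambiguous;
  a fixed-magnitude mode exists for power studies), a disease-vs-normal
  shift on 100 genes, small sex/age effects, three latent factors for
  non-genetic covariation, and gene noise variances drawn from the scaled
  inverse chi-square with $d_0 = 4$, $s_0^2 = 0.25$ — deliberately the
  family the moderation stage assumes, so $(d_0, s_0^2)$ recovery is
  testable. Latent factors inflate apparent residual variance when they
  are present, so prior-recovery experiments switch them off.
* **Phenotypes.** Four blood/bone-marrow variables (haemoglobin,
  platelets, marrow blasts, ring sideroblasts) generated on their
  transformed scales from lesion and factor coefficients — ring
  sideroblasts are wired strongly to *SF3B1*, mirroring the well-known
  clinical association — with Gaussian noise and missingness completely
  at random (5–10%).
* **Survival.** Exponential event times scaled by the group-wise log
  hazard (adverse *TP53*, *RUNX1*, *EZH2*, del(7q); protective *SF3B1*;
  age effect 0.025/year), with independent exponential censoring whose
  rate is solved numerically to hit the target censored fraction (35%
  by default). Censoring independent of covariates is the simplest
  mechanism consistent with the Cox model.

Every generator is a pure function of (config, seed); per-stage seeds are
derived independently from the global seed, so toggling one pipeline
stage never shifts another's randomness.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: probe-level microarray artifacts and
normalization effects; clonal heterogeneity (mutations present in only a
subset of cells); informative censoring; non-additive epistasis between
lesions; batch structure beyond generic latent factors; and measurement
error in the clinical variables. Results on real cohorts additionally
depend on upstream normalization, which is out of scope (the pipeline
starts from a normalized matrix with one row per gene, multiple probes
pre-averaged).

## Calibration experiment design

The test suite's statistical experiments are sized so Monte-Carlo error
is small relative to what they assert. Null FDR calibration uses the
default 150 × 2,000 cohort with 20 genotype permutations; the
moderated-F p-values are additionally checked for uniformity by a
Kolmogorov–Smirnov test. Target recovery uses n = 200 with 100
fixed-magnitude effects per lesion — note that recall there is bounded by
the rarest lesions (7–12 carriers), a genuine power limit of realistic
frequencies rather than an estimation defect. Null survival concordance
is averaged over three replicate 600-sample cohorts because a single
cohort's CV mean C carries dataset-level chance correlations (sd ≈ 0.03)
that fold averaging cannot remove. Hazard variance-share recovery uses
n = 2,000 with true shares 0.7/0.2/0.1. The expression-mediated survival
experiment uses a 130-sample cohort in which ≥ 74% of each leading
expression component is genotype-driven, so its premise — mutations act
on survival only through expression — actually holds in the simulated
data; three repeated five-fold splits are pooled before comparing
predictor classes.

## Known limitations

* The per-gene model is strictly additive in lesions; interaction terms
  would require a different design matrix and more samples than typical
  cohorts provide.
* The moment estimator of $(d_0, s_0^2)$ assumes all genes share one
  prior; robust variants that down-weight hypervariable genes are not
  implemented.
* The "GLM" for blood counts is transform-then-fit Gaussian least
  squares except for dichotomous responses; count families
  (Poisson/negative binomial) are not provided.
* The ridge Cox Hessian is dense; the implementation is comfortable to a
  few hundred covariates but is not designed for genome-wide survival
  regression.
* Risk-variance shares are signed; strongly collinear classes can make
  individual shares unstable even though their sum is exact.
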