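# genodecon

Integrative analysis of cancer cohorts that links recurrent **driver
lesions** (somatic point mutations and cytogenetic alterations, coded as
binary covariates) to **gene expression**, **diagnostic blood counts** and
**survival**. The package was built with myelodysplastic syndromes (MDS) in
mind — chronic blood cancers in which a handful of recurrent drivers
(*SF3B1*, *TET2*, *SRSF2*, del(5q), ...) reshape the CD34+ transcriptome —
but every routine is cohort-agnostic.

A synthetic-cohort generator with full ground truth is a first-class part
of the package: every statistical stage can be exercised, calibrated and
stress-tested without access to patient data.

## The models

**Expression deconvolution.** For gene *k* and patient *i*,

    Y_ik = beta_0k + sum_j X_ij * beta_jk + eps_ik,

where `X` holds the lesion indicators plus a disease-vs-normal indicator,
sex and age. One least-squares fit per gene (shared QR across all genes)
yields coefficients whose residual variances are shrunk toward a scaled
inverse chi-square prior estimated from all genes by closed-form moment
matching on log variances — the empirical-Bayes moderation that turns
ordinary t/F statistics into moderated ones with `d0` extra degrees of
freedom. Discoveries are controlled by Benjamini–Hochberg FDR; a
permutation mode re-runs the whole pipeline on genotype-shuffled data to
verify calibration. Per-gene genomic R² quantifies how much expression
variability the drivers explain.

**Co-mutation structure.** Pairwise lesion odds ratios
(Haldane-corrected) against the Jaccard overlap of the lesions'
transcriptional target sets, with a permutation test of their rank
correlation — do lesions that are mutated together also converge on the
same genes?

**Blood-count models.** Each phenotype is transformed by its value range
(identity / log / logit), then regressed on lesions + expression principal
components + demographics with a LASSO penalty solved by cyclic coordinate
descent. The penalty is chosen to maximize the five-fold cross-validated
generalized R² (Cox–Snell likelihood-ratio form, which reduces to the
classical R² for Gaussian fits), and the explained variance is attributed
to covariate groups by signed generalized components.

**Survival models.** Ridge-penalized Cox proportional hazards (Breslow
ties, Newton iterations; the single ridge precision expresses a shared
prior on coefficient variances and is chosen by inner cross-validated
partial likelihood). Prognostic value per data class is measured by
five-fold cross-validated Harrell's C; the fitted log-hazard variance is
decomposed exactly into per-class generalized components
`s_g = sum_h Cov(r_.g, r_.h)`. Genotype-predicted expression components
let a cohort without expression data borrow the transcriptome's prognostic
weighting.

## Worked example

```r
library(genodecon)

run <- run_pipeline(run_config(out_dir = "mds_run", seed = 1))
cat(readLines(file.path(run, "report.md")), sep = "\n")
```

The default configuration simulates a 150-sample cohort (15 healthy
controls) with 2,000 genes and 16 drivers, then runs every stage. The
report it printed for seed 1 (abridged):

```
## Significant genes per lesion
- SF3B1: 23
- TET2: 24
- SRSF2: 26
...
## Phenotype models
- ring_sideroblasts (logit): CV R2 = 0.569 +/- 0.021, 8 covariates
...
## Survival models
- C(genetic) = 0.626 +/- 0.024
- C(expression) = 0.621 +/- 0.021
- C(demographic) = 0.567 +/- 0.029
- risk share expression: 0.72
```

Reading this: each driver's *target set* is the genes whose moderated-t
q-value falls below 0.05 after adjusting for all other covariates; ring
sideroblasts are the best-predicted phenotype (the generator wires them to
*SF3B1*, which the LASSO duly selects first); and in the all-covariate
survival model the expression components carry ~72% of the log-hazard
variance, mirroring their configured dominance.

Individual stages are plain functions — `simulate_cohort()`,
`build_design_matrix()`, `fit_gene_models()`, `gene_fit_table()`,
`extract_target_sets()`, `structure_summary()`, `fit_phenotype_model()`,
`compare_predictor_classes()`, `decompose_risk_variance()`,
`kaplan_meier_terciles()` — see the vignette for the methods.

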