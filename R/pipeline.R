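#' Assemble a pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: the cohort source (a
#' simulation config, or a directory of cohort TSVs), stage toggles, the
#' number of expression PCs carried into phenotype and survival models,
#' the FDR level, cross-validation folds and the mandatory global seed.
#' The seed is expanded into independent per-stage streams, so toggling
#' one stage never shifts another stage's randomness.
#'
#' @param out_dir run directory to create.
#' @param seed mandatory integer seed.
#' @param sim a [sim_config()] used when `input_dir` is `NULL`.
#' @param input_dir optional directory of cohort TSVs (see
#'   [load_cohort()]).
#' @param stages subset of `c("deconvolute", "structure", "phenotypes",
#'   "survive")`.
#' @param n_pcs,fdr,folds,min_recurrence analysis parameters.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed, sim = sim_config(),
                       input_dir = NULL,
                       stages = c("deconvolute", "structure",
                                  "phenotypes", "survive"),
                       n_pcs = 20, fdr = 0.05, folds = 5,
                       min_recurrence = 5) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(all(stages %in% c("deconvolute", "structure", "phenotypes",
                              "survive")))
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 input_dir = input_dir, stages = stages, n_pcs = n_pcs,
                 fdr = fdr, folds = folds,
                 min_recurrence = min_recurrence),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, expression deconvolution, co-mutation
#' structure, phenotype models and survival models in order, writing
#' deterministic TSV outputs plus a machine-readable `manifest.json`
#' (configuration, seed, per-stage timing, input checksums) under the run
#' directory. Re-running with the same configuration and seed reproduces
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return The run directory, invisibly; intermediate objects in
#'   `attr(, "state")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timing <- list()
  tic <- function() proc.time()[["elapsed"]]
  state <- list()

  t0 <- tic()
  if (is.null(config$input_dir)) {
    sim <- simulate_cohort(config$sim, seed = config$seed)
    bundle <- sim$bundle
    state$truth <- sim$truth
  } else {
    bundle <- load_cohort(config$input_dir)
  }
  write_cohort(bundle, file.path(config$out_dir, "cohort"))
  state$bundle <- bundle
  timing$cohort <- tic() - t0

  n_pcs <- min(config$n_pcs, min(dim(bundle$expression)) - 1)
  pca <- run_pca(bundle$expression, n_pcs)
  state$pca <- pca

  if ("deconvolute" %in% config$stages) {
    t0 <- tic()
    design <- build_design_matrix(bundle,
                                  min_recurrence = config$min_recurrence)
    fits <- fit_gene_models(bundle$expression, design)
    gft <- gene_fit_table(fits)
    targets <- extract_target_sets(gft, fdr = config$fdr)
    state$design <- design
    state$gft <- gft
    state$targets <- targets
    dd <- file.path(config$out_dir, "deconvolution")
    write_tables(list(gene_fits = as.data.frame(gft),
                      pca_scores = data.frame(sample = rownames(pca$scores),
                                              pca$scores),
                      pca_variance = data.frame(
                        component = seq_along(pca$var_frac),
                        var_frac = pca$var_frac)), dd)
    write_tables(targets, file.path(dd, "target_sets"))
    timing$deconvolute <- tic() - t0
  }

  if ("structure" %in% config$stages &&
      !is.null(state$targets)) {
    t0 <- tic()
    les_cols <- names(state$design$groups)[
      state$design$groups %in% c("genetic", "cytogenetic")]
    struct <- structure_summary(
      bundle$lesions[state$design$samples, les_cols, drop = FALSE],
      state$targets, n_universe = nrow(bundle$expression),
      seed = derive_seed(config$seed, "structure"))
    state$structure <- struct
    write_tables(list(pairwise_structure = struct$pairs,
                      structure_correlation = data.frame(
                        spearman_rho = struct$rho,
                        p_perm = struct$p_perm)),
                 file.path(config$out_dir, "structure"))
    timing$structure <- tic() - t0
  }

  if ("phenotypes" %in% config$stages) {
    t0 <- tic()
    ph_rows <- list()
    attr_rows <- list()
    state$phenotypes <- list()
    for (ph in colnames(bundle$clinical)) {
      fit <- fit_phenotype_model(bundle, ph, pca = pca,
                                 n_pcs = n_pcs,
                                 min_recurrence = config$min_recurrence,
                                 folds = config$folds,
                                 seed = derive_seed(config$seed,
                                                    paste0("pheno_", ph)))
      state$phenotypes[[ph]] <- fit
      ph_rows[[ph]] <- data.frame(
        phenotype = ph, transform = fit$transform, n = fit$n,
        lambda_opt = fit$cv$lambda_opt, cv_r2 = fit$cv$r2_opt,
        cv_r2_sd = fit$cv$r2_opt_sd,
        n_selected = sum(fit$cv$beta_opt != 0))
      sh <- fit$attribution$shares
      attr_rows[[ph]] <- data.frame(phenotype = ph, group = names(sh),
                                    share = unname(sh),
                                    total_r2 = fit$attribution$total_r2)
    }
    write_tables(list(
      phenotype_models = do.call(rbind, c(ph_rows,
                                          list(make.row.names = FALSE))),
      variance_attribution = do.call(rbind, c(attr_rows,
                                              list(make.row.names = FALSE)))),
      file.path(config$out_dir, "phenotypes"))
    timing$phenotypes <- tic() - t0
  }

  if ("survive" %in% config$stages) {
    t0 <- tic()
    cmp <- compare_predictor_classes(
      bundle, n_pcs = n_pcs, min_recurrence = config$min_recurrence,
      folds = config$folds, seed = derive_seed(config$seed, "survive"),
      pca = pca)
    state$concordance <- cmp

    blocks <- survival_design_blocks(bundle, n_pcs = n_pcs,
                                     min_recurrence = config$min_recurrence,
                                     pca = pca)
    Xall <- do.call(cbind, blocks$blocks[c("genetic", "cytogenetic",
                                           "expression", "blood",
                                           "demographic")])
    groups <- unlist(lapply(c("genetic", "cytogenetic", "expression",
                              "blood", "demographic"), function(g)
      setNames(rep(g, ncol(blocks$blocks[[g]])),
               colnames(blocks$blocks[[g]]))))
    cc <- complete.cases(Xall)
    tau <- select_tau(Xall[cc, ], blocks$time[cc], blocks$status[cc],
                      tau_grid = exp(seq(log(0.25), log(256),
                                         length.out = 7)),
                      seed = derive_seed(config$seed, "tau"))
    full <- fit_ridge_cox(Xall[cc, ], blocks$time[cc], blocks$status[cc],
                          tau = tau, groups = groups)
    decomp <- decompose_risk_variance(full)
    km <- kaplan_meier_terciles(full$risk, blocks$time[cc],
                                blocks$status[cc])
    state$cox <- full
    state$decomposition <- decomp
    state$km <- km
    write_tables(list(
      concordance = as.data.frame(cmp),
      risk_decomposition = data.frame(group = names(decomp$components),
                                      s_g = unname(decomp$components),
                                      share = unname(decomp$shares)),
      km_terciles = km$curves),
      file.path(config$out_dir, "survival"))
    timing$survive <- tic() - t0
  }

  cohort_files <- sort(list.files(file.path(config$out_dir, "cohort"),
                                  full.names = TRUE))
  sums <- tools::md5sum(cohort_files)
  names(sums) <- basename(cohort_files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("genodecon")),
    seed = config$seed,
    stages = config$stages,
    parameters = config[c("n_pcs", "fdr", "folds", "min_recurrence")],
    input = if (is.null(config$input_dir)) "simulated" else config$input_dir,
    input_checksums = as.list(sums))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  # timings are run-specific; kept out of the deterministic output set
  writeLines(sprintf("%s\t%.2fs", names(timing), unlist(timing)),
             file.path(config$out_dir, "timing.log"))
  generate_report(config$out_dir)
  out <- config$out_dir
  attr(out, "state") <- state
  invisible(out)
}

#' @export
as.data.frame.gene_fit_table <- function(x, ...) {
  cols <- setdiff(colnames(x$coef), "(Intercept)")
  out <- data.frame(gene = x$genes)
  for (cl in cols) {
    out[[paste0("coef_", cl)]] <- x$coef[, cl]
    out[[paste0("t_", cl)]] <- x$t[, cl]
    out[[paste0("q_", cl)]] <- x$q[, cl]
  }
  out$F_genomic <- x$F
  out$q_F <- x$q_F
  out$r2_genomic <- x$r2_genomic
  out$r2_full <- x$r2_full
  out
}

#' Summarize a completed run into one report
#'
#' Restates the headline numbers of each stage -- cohort size, leading PCA
#' variance fractions, significant genes per lesion, the co-mutation /
#' overlap correlation, per-phenotype cross-validated R-squared with its
#' variance attribution, and per-class concordance with the risk-variance
#' decomposition -- as a single markdown document. Stages whose outputs
#' are missing are marked as explicit gaps.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return List with `path` of the written `report.md` and `complete`
#'   (logical: all six sections present).
#' @export
generate_report <- function(run_dir) {
  rd <- function(...) {
    p <- file.path(run_dir, ...)
    if (file.exists(p)) read.delim(p) else NULL
  }
  lines <- c("# Cohort analysis report", "")
  complete <- TRUE
  gap <- function(what) {
    complete <<- FALSE
    c(paste0("## ", what), "", "MISSING: stage did not run.", "")
  }

  demo <- rd("cohort", "demographics.tsv")
  if (!is.null(demo)) {
    lines <- c(lines, "## Cohort", "",
               sprintf("- samples: %d (%d controls)", nrow(demo),
                       sum(demo$normal)), "")
  } else lines <- c(lines, gap("Cohort"))

  pv <- rd("deconvolution", "pca_variance.tsv")
  if (!is.null(pv)) {
    lines <- c(lines, "## Principal components", "",
               sprintf("- PC%d: %.1f%% of variance", 1:3,
                       100 * pv$var_frac[1:3]), "")
  } else lines <- c(lines, gap("Principal components"))

  ts_dir <- file.path(run_dir, "deconvolution", "target_sets")
  if (dir.exists(ts_dir)) {
    fs <- list.files(ts_dir, pattern = "\\.tsv$")
    counts <- vapply(fs, function(f)
      nrow(read.delim(file.path(ts_dir, f))), 0L)
    lines <- c(lines, "## Significant genes per lesion", "",
               sprintf("- %s: %d", sub("\\.tsv$", "", fs), counts), "")
  } else lines <- c(lines, gap("Significant genes per lesion"))

  sc <- rd("structure", "structure_correlation.tsv")
  if (!is.null(sc)) {
    lines <- c(lines, "## Co-mutation vs target-set overlap", "",
               sprintf("- Spearman rho = %.3f (permutation p = %.3f)",
                       sc$spearman_rho, sc$p_perm), "")
  } else lines <- c(lines, gap("Co-mutation vs target-set overlap"))

  pm <- rd("phenotypes", "phenotype_models.tsv")
  if (!is.null(pm)) {
    lines <- c(lines, "## Phenotype models", "",
               sprintf("- %s (%s): CV R2 = %.3f +/- %.3f, %d covariates",
                       pm$phenotype, pm$transform, pm$cv_r2, pm$cv_r2_sd,
                       pm$n_selected), "")
  } else lines <- c(lines, gap("Phenotype models"))

  cn <- rd("survival", "concordance.tsv")
  dc <- rd("survival", "risk_decomposition.tsv")
  if (!is.null(cn) && !is.null(dc)) {
    lines <- c(lines, "## Survival models", "",
               sprintf("- C(%s) = %.3f +/- %.3f", cn$class, cn$mean_c,
                       cn$sd_mean), "",
               sprintf("- risk share %s: %.2f", dc$group, dc$share), "")
  } else lines <- c(lines, gap("Survival models"))

  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  list(path = path, complete = complete)
}
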