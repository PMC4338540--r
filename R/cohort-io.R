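#' Assemble and validate a cohort bundle
#'
#' A cohort bundle holds the five aligned tables the pipeline works on:
#' a log-scale expression matrix (genes x samples), a binary lesion matrix
#' (samples x lesions, each lesion labelled `"genetic"` or `"cytogenetic"`),
#' a clinical phenotype table with declared value domains, demographics
#' (sex, age), and right-censored survival. Samples are aligned to the
#' sorted intersection of the per-table sample sets so that the bundle is
#' deterministic regardless of input row order.
#'
#' @param expression numeric matrix, genes x samples, finite log-scale values
#'   with gene row names and sample column names.
#' @param lesions binary matrix, samples x lesions, entries 0/1.
#' @param lesion_class named character vector mapping each lesion to
#'   `"genetic"` or `"cytogenetic"`.
#' @param clinical data frame of numeric phenotype columns, row names are
#'   sample IDs; `NA` marks missing values (never imputed downstream).
#' @param clinical_domains named character vector mapping each clinical
#'   column to `"real"`, `"positive"`, `"unit-interval"` or `"binary"`.
#' @param demographics data frame with columns `sex` (1 = female) and `age`
#'   (integer years), row names are sample IDs.
#' @param survival data frame with columns `time` (days, >= 0) and `status`
#'   (1 = event), row names are sample IDs.
#' @param normal logical or 0/1 vector flagging healthy controls, named by
#'   sample ID. Controls must have all-zero lesion rows.
#'
#' @return An object of class `cohort_bundle`: a list with the components
#'   above plus `samples`, all reordered to one shared sorted sample list.
#' @export
cohort_bundle <- function(expression, lesions, lesion_class, clinical,
                          clinical_domains, demographics, survival,
                          normal) {
  expression <- as.matrix(expression)
  lesions <- as.matrix(lesions)
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(expression)))
    stop("duplicate gene IDs in expression matrix")
  if (!all(is.finite(expression)))
    stop("expression matrix contains non-finite values")
  if (!all(lesions %in% c(0, 1)))
    stop("lesion matrix entries must be 0 or 1")
  if (anyDuplicated(colnames(lesions)))
    stop("duplicate lesion names")
  if (!all(colnames(lesions) %in% names(lesion_class)))
    stop("every lesion needs a class label (genetic/cytogenetic)")
  if (!all(lesion_class %in% c("genetic", "cytogenetic")))
    stop("lesion classes must be 'genetic' or 'cytogenetic'")
  if (!all(c("time", "status") %in% colnames(survival)))
    stop("survival table needs columns 'time' and 'status'")
  if (!all(c("sex", "age") %in% colnames(demographics)))
    stop("demographics table needs columns 'sex' and 'age'")

  tabs <- list(expression = colnames(expression), lesions = rownames(lesions),
               clinical = rownames(clinical),
               demographics = rownames(demographics),
               survival = rownames(survival))
  samples <- sort(Reduce(intersect, tabs))
  if (length(samples) == 0L)
    stop("no samples shared across all cohort tables")
  dropped <- vapply(tabs, function(s) length(setdiff(s, samples)), 0L)
  if (any(dropped > 0))
    message("samples dropped during alignment: ",
            paste(names(dropped)[dropped > 0], dropped[dropped > 0],
                  sep = "=", collapse = ", "))

  normal <- as.logical(normal[samples])
  normal[is.na(normal)] <- FALSE
  names(normal) <- samples

  bundle <- structure(list(
    expression = expression[, samples, drop = FALSE],
    lesions = lesions[samples, , drop = FALSE],
    lesion_class = lesion_class[colnames(lesions)],
    clinical = clinical[samples, , drop = FALSE],
    clinical_domains = clinical_domains,
    demographics = demographics[samples, c("sex", "age"), drop = FALSE],
    survival = survival[samples, c("time", "status"), drop = FALSE],
    normal = normal,
    samples = samples
  ), class = "cohort_bundle")
  validate_cohort(bundle)
  bundle
}

#' Validate cohort bundle invariants
#'
#' Checks alignment, value domains, survival coding, and that healthy
#' controls carry no lesions. Called by [cohort_bundle()]; exported so
#' callers can re-check after manual edits.
#'
#' @param bundle a `cohort_bundle`.
#' @return The bundle, invisibly; errors describe the first violation found.
#' @export
validate_cohort <- function(bundle) {
  s <- bundle$samples
  stopifnot(identical(colnames(bundle$expression), s),
            identical(rownames(bundle$lesions), s),
            identical(rownames(bundle$clinical), s),
            identical(rownames(bundle$demographics), s),
            identical(rownames(bundle$survival), s))
  surv <- bundle$survival
  if (any(!is.na(surv$time) & surv$time < 0))
    stop("survival times must be non-negative")
  if (!all(stats::na.omit(surv$status) %in% c(0, 1)))
    stop("survival status must be 0/1")
  if (any(surv$status == 1 & is.na(surv$time), na.rm = TRUE))
    stop("missing survival time for a sample with an observed event")
  if (any(bundle$normal) &&
      any(bundle$lesions[bundle$normal, , drop = FALSE] != 0))
    stop("healthy controls must have all-zero lesion rows")
  for (v in colnames(bundle$clinical)) {
    dom <- bundle$clinical_domains[[v]]
    x <- stats::na.omit(bundle$clinical[[v]])
    bad <- switch(dom,
      real = FALSE,
      positive = any(x <= 0),
      `unit-interval` = any(x < 0 | x > 1),
      binary = !all(x %in% c(0, 1)),
      stop("unknown value domain '", dom, "' for clinical variable ", v))
    if (bad)
      stop("clinical variable '", v, "' violates its declared domain '",
           dom, "'")
  }
  invisible(bundle)
}

#' Load a cohort from tab-separated files
#'
#' Reads the standard cohort layout: `expression.tsv` (rows = genes,
#' columns = samples), `lesions.tsv` (rows = samples, columns = lesions,
#' 0/1, preceded by one `#class` metadata line assigning each lesion to
#' `genetic` or `cytogenetic`), `clinical.tsv` plus `clinical_domains.tsv`
#' (columns `variable`, `domain`), `demographics.tsv` (columns `sample`,
#' `sex`, `age`, `normal`), and `survival.tsv` (columns `sample`,
#' `time_days`, `status`). Missing values are written `NA`.
#'
#' The returned bundle's sample list is the sorted intersection of the
#' per-table sample sets; counts of dropped samples are reported.
#'
#' @param dir directory containing the cohort TSVs.
#' @return A [cohort_bundle()].
#' @export
load_cohort <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing cohort file: ", p)
    p
  }
  expr <- as.matrix(read.delim(path("expression.tsv"), row.names = 1,
                               check.names = FALSE))

  les_lines <- readLines(path("lesions.tsv"))
  class_line <- grep("^#class", les_lines, value = TRUE)
  if (length(class_line) != 1L)
    stop("lesions.tsv must contain exactly one '#class' metadata line ",
         "in file ", path("lesions.tsv"))
  les <- read.delim(text = les_lines[!startsWith(les_lines, "#")],
                    row.names = 1, check.names = FALSE)
  les <- as.matrix(les)
  if (!all(les %in% c(0, 1)))
    stop("non-binary value in lesion matrix (file lesions.tsv)")
  classes <- strsplit(sub("^#class\t", "", class_line), "\t")[[1]]
  if (length(classes) != ncol(les))
    stop("#class line length does not match lesion columns in lesions.tsv")
  lesion_class <- setNames(classes, colnames(les))

  clin <- read.delim(path("clinical.tsv"), row.names = 1, check.names = FALSE)
  dom_tab <- read.delim(path("clinical_domains.tsv"))
  if (!all(c("variable", "domain") %in% colnames(dom_tab)))
    stop("clinical_domains.tsv needs columns 'variable' and 'domain'")
  missing_dom <- setdiff(colnames(clin), dom_tab$variable)
  if (length(missing_dom))
    stop("no declared domain for clinical column(s): ",
         paste(missing_dom, collapse = ", "))
  domains <- setNames(as.character(dom_tab$domain), dom_tab$variable)

  demo <- read.delim(path("demographics.tsv"))
  for (col in c("sample", "sex", "age"))
    if (!col %in% colnames(demo))
      stop("demographics.tsv is missing required column '", col, "'")
  rownames(demo) <- demo$sample
  normal <- if ("normal" %in% colnames(demo)) {
    setNames(demo$normal == 1, demo$sample)
  } else setNames(rep(FALSE, nrow(demo)), demo$sample)

  surv <- read.delim(path("survival.tsv"))
  for (col in c("sample", "time_days", "status"))
    if (!col %in% colnames(surv))
      stop("survival.tsv is missing required column '", col, "'")
  rownames(surv) <- surv$sample
  surv <- data.frame(time = surv$time_days, status = surv$status,
                     row.names = surv$sample)

  cohort_bundle(expr, les, lesion_class, clin, domains, demo, surv, normal)
}

#' Write a cohort bundle to the standard TSV layout
#'
#' Inverse of [load_cohort()]: emits `expression.tsv`, `lesions.tsv` (with
#' its `#class` metadata line), `clinical.tsv`, `clinical_domains.tsv`,
#' `demographics.tsv` and `survival.tsv` into `dir`. Output is
#' deterministic (fixed column order, `NA` for missing) so repeated writes
#' of the same bundle are byte-identical.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file, ...) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE, ...)
  }
  wt(format_num(bundle$expression), "expression.tsv", col.names = NA)

  les_file <- file.path(dir, "lesions.tsv")
  con <- file(les_file, "w")
  writeLines(paste0("#class\t",
                    paste(bundle$lesion_class, collapse = "\t")), con)
  close(con)
  suppressWarnings(
    write.table(bundle$lesions, les_file, sep = "\t", quote = FALSE,
                col.names = NA, append = TRUE))

  wt(format_num(as.matrix(bundle$clinical)), "clinical.tsv", col.names = NA)
  wt(data.frame(variable = colnames(bundle$clinical),
                domain = unname(bundle$clinical_domains[
                  colnames(bundle$clinical)])),
     "clinical_domains.tsv", row.names = FALSE)
  wt(data.frame(sample = bundle$samples,
                sex = bundle$demographics$sex,
                age = bundle$demographics$age,
                normal = as.integer(bundle$normal)),
     "demographics.tsv", row.names = FALSE)
  wt(data.frame(sample = bundle$samples,
                time_days = format_num(bundle$survival$time),
                status = bundle$survival$status),
     "survival.tsv", row.names = FALSE)
  invisible(dir)
}

# fixed-precision formatting so rewrites are byte-identical
format_num <- function(x, digits = 8) {
  if (is.matrix(x)) {
    out <- matrix(formatC(x, digits = digits, format = "g"),
                  nrow = nrow(x), dimnames = dimnames(x))
    out[is.na(x)] <- "NA"
    return(out)
  }
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Per-analysis sample availability masks
#'
#' Complete-case filtering is per analysis: expression deconvolution needs
#' expression, lesions and non-missing demographics; survival models
#' additionally need non-missing survival; clinical models are filtered per
#' phenotype. Nothing is imputed.
#'
#' @param bundle a `cohort_bundle`.
#' @param analysis one of `"deconvolution"`, `"survival"`, `"phenotype"`.
#' @param include_normals for `"deconvolution"`, whether healthy controls
#'   enter the mask (they do: the disease indicator absorbs them).
#' @return For `"deconvolution"` and `"survival"`, a named logical vector
#'   over samples. For `"phenotype"`, a logical matrix samples x phenotypes.
#' @export
align_and_mask <- function(bundle,
                           analysis = c("deconvolution", "survival",
                                        "phenotype"),
                           include_normals = TRUE) {
  analysis <- match.arg(analysis)
  demo_ok <- !is.na(bundle$demographics$sex) & !is.na(bundle$demographics$age)
  base <- setNames(demo_ok, bundle$samples)
  if (!include_normals) base <- base & !bundle$normal
  mask <- switch(analysis,
    deconvolution = base,
    survival = base & !is.na(bundle$survival$time) &
      !is.na(bundle$survival$status) & !bundle$normal,
    phenotype = {
      m <- !is.na(as.matrix(bundle$clinical)) & base & !bundle$normal
      rownames(m) <- bundle$samples
      m
    })
  if (!any(mask))
    stop("no samples available for analysis '", analysis, "'")
  mask
}

#' Write result tables deterministically
#'
#' Writes each element of `results` (data frames or matrices) as a TSV under
#' `out_dir` with fixed column order and fixed float precision, so repeated
#' runs with the same seed produce byte-identical files. Empty tables
#' produce a header-only file, never an absent file.
#'
#' @param results named list of data frames / matrices.
#' @param out_dir output directory, created if needed.
#' @return Character vector of file paths, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(results)) || any(names(results) == ""))
    stop("'results' must be a fully named list")
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], format_num)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
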