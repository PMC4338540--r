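#' Co-mutation odds ratio for a lesion pair
#'
#' Odds ratio of the 2x2 joint presence/absence table with the
#' Haldane-Anscombe half-count correction, so zero cells never blow up:
#' `OR = ((a + 1/2)(d + 1/2)) / ((b + 1/2)(c + 1/2))` where `a` counts
#' double mutants and `d` double wild types.
#'
#' @param lesions binary samples x lesions matrix.
#' @param pair character vector of two lesion names.
#' @return The corrected odds ratio (symmetric in the pair order).
#' @export
comutation_odds_ratio <- function(lesions, pair) {
  if (!all(pair %in% colnames(lesions)))
    stop("lesion(s) not in matrix: ",
         paste(setdiff(pair, colnames(lesions)), collapse = ", "))
  x <- lesions[, pair[1]]
  y <- lesions[, pair[2]]
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
}

#' Overlap of two target gene sets
#'
#' Jaccard index `|A n B| / |A u B|`; defined as 0 when both sets are
#' empty (flagged with a `both_empty` attribute).
#'
#' @param set_a,set_b character vectors of gene IDs.
#' @return Overlap in `[0, 1]`.
#' @export
target_set_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0)
    return(structure(0, both_empty = TRUE))
  length(intersect(set_a, set_b)) / u
}

#' Hypergeometric enrichment p-value for set overlap
#'
#' Probability of observing at least the given intersection when drawing
#' `|A|` genes from a universe of `n_universe` of which `|B|` are marked.
#'
#' @param set_a,set_b gene ID vectors.
#' @param n_universe total number of genes tested.
#' @return Upper-tail hypergeometric p-value.
#' @export
overlap_enrichment_p <- function(set_a, set_b, n_universe) {
  k <- length(intersect(set_a, set_b))
  stats::phyper(k - 1, length(set_b), n_universe - length(set_b),
                length(set_a), lower.tail = FALSE)
}

#' Pairwise co-mutation and target-overlap structure
#'
#' For every lesion pair: the 2x2 co-occurrence counts, the
#' Haldane-corrected odds ratio, the Jaccard overlap of the two lesions'
#' transcriptional target sets and a hypergeometric overlap p-value;
#' plus the Spearman rank correlation between log-OR and overlap across
#' pairs, asking whether lesions that are mutated together also share
#' downstream transcriptional consequences. Its significance is assessed
#' by permuting the pair labels of the overlap values.
#'
#' @param lesions binary samples x lesions matrix.
#' @param target_sets named list of data frames (as from
#'   [extract_target_sets()]) or of gene ID vectors; names must cover the
#'   lesion columns.
#' @param n_universe universe size for the enrichment p-value (default:
#'   number of distinct genes across all sets; 1 if all empty).
#' @param n_perm permutations for the correlation p-value.
#' @param seed integer seed.
#' @return List of class `pairwise_structure`: `pairs` data frame (one row
#'   per unordered pair), `rho` (Spearman), `p_perm`.
#' @export
structure_summary <- function(lesions, target_sets, n_universe = NULL,
                              n_perm = 1000, seed = 1) {
  lns <- colnames(lesions)
  if (length(lns) < 3)
    stop("pairwise structure correlation needs at least 3 lesions")
  sets <- lapply(target_sets[lns], function(s) {
    if (is.data.frame(s)) as.character(s$gene) else as.character(s)
  })
  if (is.null(n_universe))
    n_universe <- max(1L, length(unique(unlist(sets))))

  cmb <- utils::combn(lns, 2)
  pairs <- data.frame(lesion_a = cmb[1, ], lesion_b = cmb[2, ])
  pairs$n_both <- pairs$n_a_only <- pairs$n_b_only <- pairs$n_neither <- NA
  pairs$odds_ratio <- pairs$overlap <- pairs$enrichment_p <- NA_real_
  pairs$size_a <- lengths(sets)[pairs$lesion_a]
  pairs$size_b <- lengths(sets)[pairs$lesion_b]
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$lesion_a[i]; b <- pairs$lesion_b[i]
    x <- lesions[, a]; y <- lesions[, b]
    pairs$n_both[i] <- sum(x & y)
    pairs$n_a_only[i] <- sum(x & !y)
    pairs$n_b_only[i] <- sum(!x & y)
    pairs$n_neither[i] <- sum(!x & !y)
    pairs$odds_ratio[i] <- comutation_odds_ratio(lesions, c(a, b))
    pairs$overlap[i] <- target_set_overlap(sets[[a]], sets[[b]])
    pairs$enrichment_p[i] <- overlap_enrichment_p(sets[[a]], sets[[b]],
                                                  n_universe)
  }

  rho <- suppressWarnings(
    cor(log(pairs$odds_ratio), pairs$overlap, method = "spearman"))
  set.seed(seed)
  perm_rho <- replicate(n_perm, suppressWarnings(
    cor(log(pairs$odds_ratio), sample(pairs$overlap),
        method = "spearman")))
  p_perm <- (1 + sum(abs(perm_rho) >= abs(rho), na.rm = TRUE)) /
    (1 + n_perm)
  structure(list(pairs = pairs, rho = rho, p_perm = p_perm),
            class = "pairwise_structure")
}

#' Venn region counts for up to 4 target sets
#'
#' Counts every membership pattern of the given sets; region counts sum to
#' the union cardinality.
#'
#' @param sets named list of gene ID vectors (2 to 4 sets).
#' @return Data frame with one row per non-empty membership pattern:
#'   indicator columns per set and `count`.
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) >= 2, length(sets) <= 4,
            !is.null(names(sets)))
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL,
                                                             names(sets)))
  pat <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pat)
  out <- do.call(rbind, lapply(names(tab), function(p) {
    bits <- as.integer(strsplit(p, "")[[1]])
    setNames(as.data.frame(t(bits)), names(sets))
  }))
  out$count <- as.integer(tab)
  out
}
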