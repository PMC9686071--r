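# Inferential layer: methylated fraction across variability quartiles,
# one-tailed rank tests, fold-change correlations, hypergeometric set
# overlap, score comparisons against size-matched random gene sets, and the
# heat-response fold-change matrix.

#' Fraction of methylated transcripts per variability quartile
#'
#' @param quartiles named factor from [variability_quartiles()].
#' @param methylated_set character vector of methylated gene ids (sharing
#'   the quartile map's gene universe).
#' @return Data frame of class `quartile_fraction_table`: `quartile`,
#'   `n_genes`, `n_methylated`, `fraction`, plus attribute `monotone`
#'   (logical: are fractions non-increasing Q1 to Q4? reported, not
#'   asserted).
#' @export
fraction_methylated_by_quartile <- function(quartiles, methylated_set) {
  tab <- table(quartiles)
  if (any(tab == 0)) stop("empty quartile: ", names(tab)[tab == 0][1])
  meth <- names(quartiles) %in% methylated_set
  n_meth <- tapply(meth, quartiles, sum)
  out <- data.frame(quartile = names(tab), n_genes = as.integer(tab),
                    n_methylated = as.integer(n_meth),
                    fraction = as.numeric(n_meth / tab),
                    stringsAsFactors = FALSE)
  class(out) <- c("quartile_fraction_table", "data.frame")
  attr(out, "monotone") <- all(diff(out$fraction) <= 0)
  out
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Mann-Whitney/Wilcoxon rank-sum test via [stats::wilcox.test()]: the exact
#' null distribution when the pooled sample size is at most 20 and there are
#' no ties, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"less"` or `"greater"` (the direction must be chosen
#'   from the scientific claim; there is no default).
#' @return Object of class `rank_test`: `statistic` (Mann-Whitney U),
#'   `p_value`, `alternative`, `n_x`, `n_y`, `exact`.
#' @export
rank_test_one_tailed <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty input sample")
  no_ties <- !anyDuplicated(c(x, y))
  use_exact <- (length(x) + length(y)) <= 20 && no_ties
  ht <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = use_exact, correct = TRUE)
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 alternative = alternative, n_x = length(x),
                 n_y = length(y), exact = use_exact),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf(
    "<rank_test> one-tailed Wilcoxon rank-sum (%s), U = %g, p = %.4g (n = %d vs %d, %s)\n",
    x$alternative, x$statistic, x$p_value, x$n_x, x$n_y,
    if (x$exact) "exact" else "normal approx."))
  invisible(x)
}

#' Correlation between heat-induced expression change and m6A change
#'
#' For each tissue x genotype contrast with both conditions present,
#' computes the per-gene log2 fold change of input expression (HS/CS, with
#' pseudocount) and the change in m6A enrichment (HS - CS), and reports
#' their Pearson correlation.
#'
#' @param expr an [expression_matrix()] with CS and HS samples.
#' @param pseudocount FPKM offset shared with the methylation module.
#' @return Data frame: `tissue`, `genotype`, `r`, `n`.
#' @export
fc_correlation <- function(expr, pseudocount = 0.1) {
  enr <- enrichment_table(expr, pseudocount)
  sm <- expr$samples
  combos <- unique(sm[, c("tissue", "genotype")])
  out <- NULL
  for (i in seq_len(nrow(combos))) {
    ti <- combos$tissue[i]; ge <- combos$genotype[i]
    grp <- function(cond) paste(ti, cond, ge, sep = ".")
    sel_cs <- group_label(sm) == grp("CS") & sm$fraction == "input"
    sel_hs <- group_label(sm) == grp("HS") & sm$fraction == "input"
    if (!any(sel_cs) || !any(sel_hs)) next
    fc <- log2((rowMeans(expr$values[, sel_hs, drop = FALSE]) + pseudocount) /
                 (rowMeans(expr$values[, sel_cs, drop = FALSE]) + pseudocount))
    e_cs <- enr$enrichment[enr$group == grp("CS")]
    e_hs <- enr$enrichment[enr$group == grp("HS")]
    if (!length(e_cs) || !length(e_hs)) next
    de <- e_hs - e_cs
    ok <- is.finite(fc) & is.finite(de)
    if (sum(ok) < 3) stop("fewer than 3 shared genes in contrast ",
                          ti, "/", ge)
    out <- rbind(out, data.frame(tissue = ti, genotype = ge,
                                 r = stats::cor(fc[ok], de[ok]),
                                 n = sum(ok), stringsAsFactors = FALSE))
  }
  out
}

#' Hypergeometric set-overlap test
#'
#' Upper-tail probability of observing at least the actual overlap between
#' two gene sets drawn from a shared universe, P(X >= k) with
#' N = |universe|, K = |set_a|, n = |set_b|, plus fold enrichment
#' (observed / expected overlap).
#'
#' @param set_a,set_b character vectors, both subsets of `universe`.
#' @param universe character vector of all eligible gene ids.
#' @return List: `overlap`, `expected`, `fold_enrichment`, `p_value`,
#'   `n_universe`, `n_a`, `n_b`.
#' @export
set_overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe)) stop("set_a not contained in universe")
  if (!all(set_b %in% universe)) stop("set_b not contained in universe")
  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expected <- K * n / N
  list(overlap = k, expected = expected,
       fold_enrichment = if (expected > 0) k / expected else NA_real_,
       p_value = p, n_universe = N, n_a = K, n_b = n)
}

#' Compare a gene set's scores against a size-matched random set
#'
#' One-tailed rank test of the set's scores against the scores of an
#' equally sized random draw (without replacement, seeded) from the
#' universe excluding the set. The random draw is returned so the baseline
#' is reproducible.
#'
#' @param gene_set character vector of gene ids.
#' @param score_table named numeric vector covering the universe.
#' @param alternative `"greater"` if the set is claimed to score higher
#'   than random, `"less"` otherwise.
#' @param n_random number of random draws; with more than one, the median
#'   p-value and all per-draw p-values are reported.
#' @param seed integer seed for the draw(s).
#' @return A `rank_test` (first draw) with extra fields `random_draws`
#'   (list of gene-id vectors) and `p_values` (per draw).
#' @export
score_comparison <- function(gene_set, score_table,
                             alternative = c("greater", "less"),
                             n_random = 1, seed = 1) {
  alternative <- match.arg(alternative)
  universe <- names(score_table)
  if (is.null(universe)) stop("score_table must be a named vector")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe))
    stop("gene_set not covered by score_table")
  pool <- setdiff(universe, gene_set)
  if (length(gene_set) > length(pool))
    stop("gene_set larger than half the universe: cannot size-match")
  draws <- with_seed(seed, lapply(seq_len(n_random), function(i)
    sample(pool, length(gene_set))))
  tests <- lapply(draws, function(d)
    rank_test_one_tailed(score_table[gene_set], score_table[d], alternative))
  out <- tests[[1]]
  out$random_draws <- draws
  out$p_values <- vapply(tests, `[[`, numeric(1), "p_value")
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Heat-response fold-change matrix
#'
#' Selects genes heat-activated in wild-type leaves (input-fraction log2
#' fold change HS/CS at least `log2(selection_fold)`; the boundary is
#' inclusive) and tabulates their log2 fold change in every tissue x
#' genotype, columns ordered wt leaf, wt flower, mutant leaf, mutant
#' flower.
#'
#' @param expr an [expression_matrix()].
#' @param selection_fold fold-change selection threshold (default 2).
#' @param pseudocount FPKM offset for the fold changes.
#' @return Object of class `heat_response_matrix`: `values` (genes x
#'   groups log2FC matrix), `column_means`.
#' @export
heat_response_matrix <- function(expr, selection_fold = 2,
                                 pseudocount = 0.1) {
  sm <- expr$samples
  cols <- data.frame(tissue = c("leaf", "flower", "leaf", "flower"),
                     genotype = c("wt", "wt", "mutant", "mutant"),
                     stringsAsFactors = FALSE)
  colnames_out <- paste(cols$genotype, cols$tissue, sep = ".")
  fcs <- matrix(NA_real_, nrow = nrow(expr$values), ncol = 4,
                dimnames = list(rownames(expr$values), colnames_out))
  for (i in 1:4) {
    grp <- function(cond) paste(cols$tissue[i], cond, cols$genotype[i],
                                sep = ".")
    sel_cs <- group_label(sm) == grp("CS") & sm$fraction == "input"
    sel_hs <- group_label(sm) == grp("HS") & sm$fraction == "input"
    if (!any(sel_cs) || !any(sel_hs))
      stop("missing group for heat-response matrix: ", grp("CS"), " / ",
           grp("HS"))
    fcs[, i] <- log2(
      (rowMeans(expr$values[, sel_hs, drop = FALSE]) + pseudocount) /
        (rowMeans(expr$values[, sel_cs, drop = FALSE]) + pseudocount))
  }
  keep <- fcs[, "wt.leaf"] >= log2(selection_fold)
  if (!any(keep)) warning("no gene passes the heat-activation selection")
  vals <- fcs[keep, , drop = FALSE]
  structure(list(values = vals,
                 column_means = colMeans(vals),
                 selection_fold = selection_fold),
            class = "heat_response_matrix")
}

#' @export
print.heat_response_matrix <- function(x, ...) {
  cat(sprintf(
    "<heat_response_matrix> %d heat-activated genes (wt-leaf FC >= %g)\n",
    nrow(x$values), x$selection_fold))
  print(round(x$column_means, 3))
  invisible(x)
}

#' Benjamini-Hochberg adjustment helper
#'
#' Thin wrapper over [stats::p.adjust()] for users running many term
#' enrichments with [set_overlap_test()].
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values (FDR).
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
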