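# m6A enrichment scoring (log2 IP/input), methylated-transcript calls,
# replicate-reproducible peak filtering, peak-to-gene assignment and
# differential (demethylase-mutant vs wild type) enrichment.

#' m6A enrichment score
#'
#' log2 fold change of immunoprecipitated over input abundance:
#' `log2((mean(ip) + pseudocount) / (mean(input) + pseudocount))`. With both
#' means zero and pseudocount zero the score is undefined and `NA` is
#' returned.
#'
#' @param ip_values replicate FPKMs of the IP fraction.
#' @param input_values replicate FPKMs of the input fraction.
#' @param pseudocount nonnegative FPKM offset guarding against zero
#'   denominators (default 0.1).
#' @return log2 enrichment (scalar), `NA` if undefined.
#' @export
enrichment_score <- function(ip_values, input_values, pseudocount = 0.1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (!length(ip_values) || !length(input_values))
    stop("empty replicate set")
  ip <- mean(ip_values) + pseudocount
  inp <- mean(input_values) + pseudocount
  if (ip == 0 && inp == 0) return(NA_real_)
  if (inp == 0) return(Inf)
  if (ip == 0) return(-Inf)
  log2(ip / inp)
}

#' Per-gene, per-group m6A enrichment table
#'
#' Averages IP and input replicates per gene within each sample group and
#' scores enrichment with [enrichment_score()]. A gene is called methylated
#' when its enrichment is strictly greater than `threshold` (default 0).
#'
#' @param expr an [expression_matrix()] containing both `input` and `ip`
#'   fraction samples.
#' @param pseudocount see [enrichment_score()].
#' @param threshold methylation-call threshold on the log2 score.
#' @return Data frame of class `enrichment_table`: `gene_id`, `group`,
#'   `ip_mean`, `input_mean`, `enrichment`, `methylated`.
#' @export
enrichment_table <- function(expr, pseudocount = 0.1, threshold = 0) {
  sm <- expr$samples
  groups <- unique(group_label(sm))
  recs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    ip_sel <- group_label(sm) == g & sm$fraction == "IP"
    in_sel <- group_label(sm) == g & sm$fraction == "input"
    if (!any(ip_sel) || !any(in_sel))
      stop("group ", g, " lacks IP or input samples")
    ip_mean <- rowMeans(expr$values[, ip_sel, drop = FALSE])
    in_mean <- rowMeans(expr$values[, in_sel, drop = FALSE])
    enr <- log2((ip_mean + pseudocount) / (in_mean + pseudocount))
    enr[ip_mean + pseudocount == 0 & in_mean + pseudocount == 0] <- NA_real_
    recs[[i]] <- data.frame(gene_id = rownames(expr$values), group = g,
                            ip_mean = ip_mean, input_mean = in_mean,
                            enrichment = enr,
                            methylated = !is.na(enr) & enr > threshold,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "pseudocount") <- pseudocount
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> %d gene x group records\n", nrow(x)))
  print(stats::aggregate(methylated ~ group, as.data.frame(x), sum))
  invisible(x)
}

#' Call methylated genes
#'
#' Genes with enrichment strictly greater than the threshold.
#'
#' @param records an [enrichment_table()].
#' @param threshold log2 enrichment threshold (default 0).
#' @param group optional group label to restrict to.
#' @return Character vector of methylated gene ids; the per-group counts are
#'   attached as attribute `counts`.
#' @export
call_methylated <- function(records, threshold = 0, group = NULL) {
  if (!is.null(group)) records <- records[records$group %in% group, ]
  sel <- !is.na(records$enrichment) & records$enrichment > threshold
  counts <- stats::aggregate(sel, by = list(group = records$group), FUN = sum)
  names(counts)[2] <- "n_methylated"
  out <- unique(records$gene_id[sel])
  attr(out, "counts") <- counts
  out
}

#' Replicate-reproducible peaks
#'
#' Retains every rep1 peak that overlaps (>= 1 bp, same chromosome) at least
#' one rep2 peak. The output interval is the union of the overlapping pair
#' and the output score the mean of the two scores; each rep2 peak is
#' consumed at most once, matching greedily by ascending coordinate.
#'
#' @param rep1,rep2 [peak_set()]s from the same sample group (their sample
#'   keys, if present, must agree on tissue/condition/genotype).
#' @return A [peak_set()] of merged reproducible peaks.
#' @export
reproducible_peaks <- function(rep1, rep2) {
  k1 <- attr(rep1, "sample_key"); k2 <- attr(rep2, "sample_key")
  if (!is.null(k1) && !is.null(k2)) {
    g1 <- k1[c("tissue", "condition", "genotype")]
    g2 <- k2[c("tissue", "condition", "genotype")]
    if (!identical(g1, g2))
      stop("replicate peak sets come from different groups: ",
           paste(unlist(g1), collapse = "."), " vs ",
           paste(unlist(g2), collapse = "."))
  }
  o1 <- order(rep1$chrom, rep1$start, rep1$end)
  o2 <- order(rep2$chrom, rep2$start, rep2$end)
  r1 <- rep1[o1, , drop = FALSE]
  r2 <- rep2[o2, , drop = FALSE]
  used <- logical(nrow(r2))
  out <- vector("list", nrow(r1))
  for (i in seq_len(nrow(r1))) {
    cand <- which(!used & r2$chrom == r1$chrom[i] &
                    r2$start < r1$end[i] & r2$end > r1$start[i])
    if (!length(cand)) next
    j <- cand[1]  # ascending coordinate order
    used[j] <- TRUE
    out[[i]] <- data.frame(chrom = r1$chrom[i],
                           start = min(r1$start[i], r2$start[j]),
                           end = max(r1$end[i], r2$end[j]),
                           name = r1$name[i],
                           score = (r1$score[i] + r2$score[j]) / 2,
                           strand = r1$strand[i],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(peak_set(sample_key = attr(rep1, "sample_key")))
  df <- do.call(rbind, out)
  peak_set(df$chrom, df$start, df$end, df$name, df$score, df$strand,
           sample_key = attr(rep1, "sample_key"))
}

#' Assign peaks to genes by midpoint
#'
#' A peak is assigned to the gene whose transcript span (5'UTR start to
#' 3'UTR end) contains the peak midpoint. When overlapping genes both
#' contain the midpoint, the gene with the largest overlap with the full
#' peak interval wins; remaining ties go to the lexicographically first
#' gene id. Unassigned peaks are counted.
#'
#' @param peaks a [peak_set()].
#' @param models a `transcript_models` list.
#' @return List with `counts` (named integer vector over all genes),
#'   `assignment` (character vector, `NA` for unassigned, parallel to
#'   `peaks` rows) and `n_unassigned`.
#' @export
assign_peaks <- function(peaks, models) {
  spans <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    start = vapply(models, function(m) tx_span(m)[1], numeric(1)),
    end = vapply(models, function(m) tx_span(m)[2], numeric(1)),
    stringsAsFactors = FALSE)
  mid <- floor((peaks$start + peaks$end) / 2)
  assignment <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    hit <- which(spans$chrom == peaks$chrom[i] &
                   spans$start <= mid[i] & mid[i] < spans$end)
    if (!length(hit)) next
    if (length(hit) > 1) {
      ov <- pmin(spans$end[hit], peaks$end[i]) -
        pmax(spans$start[hit], peaks$start[i])
      hit <- hit[ov == max(ov)]
      if (length(hit) > 1) hit <- hit[order(spans$gene_id[hit])][1]
    }
    assignment[i] <- spans$gene_id[hit]
  }
  counts <- table(factor(assignment, levels = sort(spans$gene_id)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, assignment = assignment,
       n_unassigned = sum(is.na(assignment)))
}

#' Differential m6A enrichment (mutant vs wild type)
#'
#' Per gene, `delta = enrichment(mutant) - enrichment(wt)`; a gene is
#' flagged regulated when delta is at least `log2(fold_threshold)` (the
#' boundary is inclusive: an "at least two-fold" increase includes exactly
#' two-fold). Genes with undefined enrichment in either genotype are dropped
#' and counted.
#'
#' @param wt_records,mutant_records [enrichment_table()] rows for one group
#'   each (same tissue/condition, differing genotype).
#' @param fold_threshold fold-change threshold (> 1; default 2).
#' @return Data frame `gene_id`, `delta_enrichment`, `regulated`, with
#'   attribute `n_dropped`.
#' @export
differential_enrichment <- function(wt_records, mutant_records,
                                    fold_threshold = 2) {
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1")
  shared <- intersect(wt_records$gene_id, mutant_records$gene_id)
  if (!length(shared)) stop("disjoint gene universes")
  wt <- wt_records[match(shared, wt_records$gene_id), ]
  mu <- mutant_records[match(shared, mutant_records$gene_id), ]
  ok <- !is.na(wt$enrichment) & !is.na(mu$enrichment) &
    is.finite(wt$enrichment) & is.finite(mu$enrichment)
  delta <- mu$enrichment[ok] - wt$enrichment[ok]
  out <- data.frame(gene_id = shared[ok], delta_enrichment = delta,
                    regulated = delta >= log2(fold_threshold),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!ok)
  out
}
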