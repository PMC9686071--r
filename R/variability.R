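# Gene expression variability: squared coefficient of variation over
# biological replicates, and HVG/LVG classification by log2(CV^2) thresholds.

#' Squared coefficient of variation of replicate FPKMs
#'
#' CV is the ratio of the sample standard deviation (denominator n-1) to the
#' mean; CV^2 = (scale * sd / mean)^2. A zero mean leaves CV^2 undefined
#' (returned as `NA`, not an error): variability of an unexpressed gene has
#' no meaning.
#'
#' @param values numeric vector of replicate FPKMs (>= 2 values, all >= 0).
#' @param scale multiplier applied to CV before squaring; 1 for the
#'   dimensionless CV, 100 for a percent-CV reading.
#' @return A list with `mean`, `sd` and `cv2` (`NA` when mean is 0).
#' @export
cv_squared <- function(values, scale = 1) {
  if (length(values) < 2) stop("need at least 2 replicate values")
  if (any(values < 0)) stop("negative FPKM value")
  m <- mean(values)
  s <- stats::sd(values)
  cv2 <- if (m == 0) NA_real_ else (scale * s / m)^2
  list(mean = m, sd = s, cv2 = cv2)
}

#' HVG/LVG classification thresholds
#'
#' @param hvg_min log2(CV^2) above which a gene is a highly variable gene.
#' @param lvg_max log2(CV^2) below which a gene is a lowly variable gene.
#' @param cv_scale multiplier applied to CV before squaring (see
#'   [cv_squared()]). Defaults follow the source analysis's printed
#'   thresholds (5 and -10); note that with 3 nonnegative replicates,
#'   CV^2 <= 3 under the dimensionless reading, so the default HVG threshold
#'   is only reachable under a rescaled CV — both thresholds and the scale
#'   are parameters for that reason.
#' @return A list of class `variability_thresholds`.
#' @export
variability_thresholds <- function(hvg_min = 5, lvg_max = -10, cv_scale = 1) {
  if (!(hvg_min > lvg_max)) stop("hvg_min must exceed lvg_max")
  if (!(cv_scale > 0)) stop("cv_scale must be positive")
  structure(list(hvg_min = hvg_min, lvg_max = lvg_max, cv_scale = cv_scale),
            class = "variability_thresholds")
}

#' Classify a gene by its log2(CV^2)
#'
#' `log2cv2 > hvg_min` is HVG; `log2cv2 < lvg_max` is LVG (`-Inf`, from a
#' zero-sd gene, qualifies: a gene with no replicate noise is the extreme
#' lowly variable case); anything between is `neither`; an undefined CV^2
#' (`NA`, zero-mean gene) is `undefined`.
#'
#' @param log2cv2 numeric vector (may contain `-Inf` and `NA`).
#' @param thresholds a [variability_thresholds()].
#' @return Character vector over `{"HVG","LVG","neither","undefined"}`.
#' @export
classify_variability <- function(log2cv2,
                                 thresholds = variability_thresholds()) {
  out <- rep("neither", length(log2cv2))
  out[log2cv2 > thresholds$hvg_min] <- "HVG"
  out[log2cv2 < thresholds$lvg_max] <- "LVG"
  out[is.na(log2cv2)] <- "undefined"
  out
}

#' Per-gene, per-group variability table
#'
#' Computes mean, sd, CV^2 and log2(CV^2) for every gene in every sample
#' group (tissue x condition x genotype) of the input fraction, and
#' classifies each gene as HVG/LVG/neither/undefined. Genes whose group mean
#' FPKM falls below `min_fpkm` are classified `undefined` rather than
#' dropped: CV^2 of near-zero genes is numerically unstable.
#'
#' @param expr an [expression_matrix()]; only `fraction == "input"` samples
#'   are used.
#' @param thresholds a [variability_thresholds()].
#' @param min_fpkm minimum group-mean FPKM for classification (default 1).
#' @return A data frame of class `variability_table` with columns `gene_id`,
#'   `group`, `mean`, `sd`, `cv2`, `log2cv2`, `class`, and a `counts`
#'   attribute giving per-group HVG/LVG counts.
#' @export
variability_table <- function(expr, thresholds = variability_thresholds(),
                              min_fpkm = 1) {
  input <- expr$samples$fraction == "input"
  if (!any(input)) stop("no input-fraction samples")
  samples <- expr$samples[input, , drop = FALSE]
  vals <- expr$values[, input, drop = FALSE]
  groups <- unique(group_label(samples))
  recs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    sel <- group_label(samples) == g
    if (sum(sel) < 2)
      stop("group ", g, " has fewer than 2 input replicates")
    v <- vals[, sel, drop = FALSE]
    m <- rowMeans(v)
    s <- apply(v, 1, stats::sd)
    cv2 <- ifelse(m == 0, NA_real_, (thresholds$cv_scale * s / m)^2)
    log2cv2 <- ifelse(is.na(cv2), NA_real_,
                      ifelse(cv2 == 0, -Inf, log2(cv2)))
    cls <- classify_variability(log2cv2, thresholds)
    cls[!is.na(m) & m < min_fpkm] <- "undefined"
    recs[[i]] <- data.frame(gene_id = rownames(vals), group = g,
                            mean = m, sd = s, cv2 = cv2, log2cv2 = log2cv2,
                            class = cls, row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  counts <- do.call(rbind, lapply(groups, function(g) {
    cls <- out$class[out$group == g]
    data.frame(group = g, n_hvg = sum(cls == "HVG"),
               n_lvg = sum(cls == "LVG"), stringsAsFactors = FALSE)
  }))
  class(out) <- c("variability_table", "data.frame")
  attr(out, "counts") <- counts
  attr(out, "thresholds") <- thresholds
  out
}

#' @export
print.variability_table <- function(x, ...) {
  cat(sprintf("<variability_table> %d gene x group records\n", nrow(x)))
  print(attr(x, "counts"))
  invisible(x)
}

#' Per-gene variability difference between two groups
#'
#' Delta = log2cv2(group_b) - log2cv2(group_a). Genes with undefined CV^2
#' in either group are dropped; the number dropped is returned as an
#' attribute.
#'
#' @param expr an [expression_matrix()].
#' @param group_a,group_b group labels `"tissue.condition.genotype"`.
#' @param thresholds a [variability_thresholds()] (controls `cv_scale`).
#' @return Named numeric vector of per-gene differences with attribute
#'   `n_dropped`.
#' @export
variability_difference <- function(expr, group_a, group_b,
                                   thresholds = variability_thresholds()) {
  vt <- variability_table(expr, thresholds, min_fpkm = 0)
  for (g in c(group_a, group_b))
    if (!g %in% vt$group) stop("unknown group: ", g)
  a <- vt[vt$group == group_a, ]
  b <- vt[vt$group == group_b, ]
  stopifnot(identical(a$gene_id, b$gene_id))
  ok <- !is.na(a$log2cv2) & !is.na(b$log2cv2) &
    is.finite(a$log2cv2) & is.finite(b$log2cv2)
  delta <- b$log2cv2[ok] - a$log2cv2[ok]
  names(delta) <- a$gene_id[ok]
  attr(delta, "n_dropped") <- sum(!ok)
  delta
}

#' Assign genes to variability quartiles
#'
#' Genes are ranked by log2(CV^2) ascending (Q1 = least variable, Q4 = most
#' variable); ties are broken by gene id; quartile sizes differ by at most
#' one. Genes with undefined CV^2 are excluded.
#'
#' @param records a [variability_table()] restricted to one group, or any
#'   data frame with `gene_id` and `log2cv2` columns.
#' @return Named factor mapping gene id to `Q1`..`Q4`.
#' @export
variability_quartiles <- function(records) {
  ok <- !is.na(records$log2cv2)
  records <- records[ok, , drop = FALSE]
  n <- nrow(records)
  if (n < 4) stop("need at least 4 genes with defined CV^2")
  ord <- order(records$log2cv2, records$gene_id)
  sizes <- diff(floor(n * (0:4) / 4))
  q <- factor(rep(paste0("Q", 1:4), times = sizes),
              levels = paste0("Q", 1:4))
  out <- q[order(ord)]  # invert the permutation
  names(out) <- records$gene_id
  out
}
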