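# Metagene profiling: project peak midpoints onto a composite
# 5'UTR | CDS | 3'UTR axis with fixed region widths and estimate a smoothed
# peak-density profile comparable across samples.

#' Composite transcript coordinate of a genomic position
#'
#' Converts a genomic offset inside a transcript to a coordinate on the
#' composite [0,1) axis obtained by concatenating the 5'UTR, CDS and 3'UTR
#' with fixed widths (default 0.25/0.5/0.25). The conversion is
#' strand-aware: on the minus strand genomic order is reversed so that 0 is
#' always the transcript 5' end. A position falling in a gap between
#' regions (an intron or annotation gap inside the span) snaps to the
#' nearest region edge. Within a region, `relative = offset / length`, so
#' the first CDS base maps exactly to the 5'UTR/CDS boundary.
#'
#' @param midpoint genomic offset (0-based) within the transcript span.
#' @param model a [transcript_model()].
#' @param widths composite widths of (utr5, cds, utr3); must sum to 1.
#' @return List with `region`, `relative` (in [0,1)) and `composite`
#'   (in [0,1)).
#' @export
composite_position <- function(midpoint, model,
                               widths = c(utr5 = 0.25, cds = 0.5,
                                          utr3 = 0.25)) {
  if (abs(sum(widths) - 1) > 1e-9) stop("widths must sum to 1")
  span <- tx_span(model)
  if (midpoint < span[1] || midpoint >= span[2])
    stop("midpoint ", midpoint, " outside transcript span of ",
         model$gene_id)
  minus <- model$strand == "-"
  region_names <- c("utr5", "cds", "utr3")
  # locate the region (or snap to the nearest region edge)
  hit_region <- NA_character_; hit_pos <- NA_real_
  best_dist <- Inf; best_region <- NA_character_; best_pos <- NA_real_
  for (rn in region_names) {
    r <- model[[rn]]
    if (nrow(r) == 0) next
    inside <- which(r$start <= midpoint & midpoint < r$end)
    if (length(inside)) { hit_region <- rn; hit_pos <- midpoint; break }
    for (k in seq_len(nrow(r))) {
      for (edge in c(r$start[k], r$end[k] - 1)) {
        d <- abs(midpoint - edge)
        if (d < best_dist) {
          best_dist <- d; best_region <- rn; best_pos <- edge
        }
      }
    }
  }
  if (is.na(hit_region)) { hit_region <- best_region; hit_pos <- best_pos }
  r <- model[[hit_region]]
  len <- sum(r$end - r$start)
  # transcript-orientation offset within the region
  if (!minus) {
    off <- 0
    for (k in seq_len(nrow(r))) {
      if (hit_pos >= r$end[k]) { off <- off + (r$end[k] - r$start[k]); next }
      off <- off + (hit_pos - r$start[k]); break
    }
  } else {
    off <- 0
    for (k in rev(seq_len(nrow(r)))) {
      if (hit_pos < r$start[k]) { off <- off + (r$end[k] - r$start[k]); next }
      off <- off + (r$end[k] - 1 - hit_pos); break
    }
  }
  relative <- off / len
  cum <- c(utr5 = 0, cds = unname(widths["utr5"]),
           utr3 = unname(widths["utr5"] + widths["cds"]))
  composite <- cum[[hit_region]] + relative * widths[[hit_region]]
  list(region = hit_region, relative = relative, composite = composite)
}

#' Metagene peak-density profile
#'
#' Assigns peaks to genes ([assign_peaks()]), maps each assigned peak
#' midpoint to the composite transcript axis ([composite_position()]),
#' histograms the positions over uniform bins, smooths with a discrete
#' Gaussian kernel using reflecting boundaries (a transcript has ends;
#' density must not leak across them) and normalizes to unit area. Profiles
#' computed with the same `bins`/`widths` share bin edges and are directly
#' comparable across samples.
#'
#' @param peaks a [peak_set()].
#' @param models a `transcript_models` list.
#' @param bins number of uniform bins over [0,1) (>= 10; default 100).
#' @param smoothing_sigma Gaussian kernel sd in bins (0 disables; default 2).
#' @param widths composite region widths, see [composite_position()].
#' @return Object of class `metagene_profile`: `bin_edges`, `bin_centers`,
#'   `density` (sums to 1 when multiplied by the bin width), `boundaries`
#'   (composite coordinates of the utr5/cds and cds/utr3 junctions),
#'   `n_peaks`.
#' @export
metagene_density <- function(peaks, models, bins = 100, smoothing_sigma = 2,
                             widths = c(utr5 = 0.25, cds = 0.5,
                                        utr3 = 0.25)) {
  if (bins < 10) stop("bins must be >= 10")
  edges <- seq(0, 1, length.out = bins + 1)
  boundaries <- c(utr5_cds = unname(widths["utr5"]),
                  cds_utr3 = unname(widths["utr5"] + widths["cds"]))
  empty <- structure(list(bin_edges = edges,
                          bin_centers = (edges[-1] + edges[-(bins + 1)]) / 2,
                          density = rep(0, bins), boundaries = boundaries,
                          n_peaks = 0L),
                     class = "metagene_profile")
  if (nrow(peaks) == 0) {
    warning("empty peak set: all-zero metagene profile")
    return(empty)
  }
  asg <- assign_peaks(peaks, models)
  ok <- !is.na(asg$assignment)
  if (!any(ok)) {
    warning("no assignable peaks: all-zero metagene profile")
    return(empty)
  }
  mids <- floor((peaks$start + peaks$end) / 2)[ok]
  genes <- asg$assignment[ok]
  pos <- vapply(seq_along(mids), function(i)
    composite_position(mids[i], models[[genes[i]]], widths)$composite,
    numeric(1))
  counts <- tabulate(pmin(bins, floor(pos * bins) + 1L), nbins = bins)
  if (smoothing_sigma > 0) {
    radius <- max(1L, ceiling(4 * smoothing_sigma))
    kern <- exp(-((-radius:radius)^2) / (2 * smoothing_sigma^2))
    kern <- kern / sum(kern)
    padded <- c(rev(counts[seq_len(radius)]), counts,
                rev(counts[bins + 1 - seq_len(radius)]))
    sm <- vapply(seq_len(bins), function(b)
      sum(padded[b:(b + 2 * radius)] * kern), numeric(1))
  } else sm <- counts
  width <- 1 / bins
  dens <- sm / (sum(sm) * width)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-(bins + 1)]) / 2,
                 density = dens, boundaries = boundaries,
                 n_peaks = sum(ok)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d bins, %d peaks; argmax at %.3f\n",
              length(x$density), x$n_peaks,
              x$bin_centers[which.max(x$density)]))
  invisible(x)
}

#' Plot a metagene profile
#'
#' Draws the density curve with dashed lines at the 5'UTR/CDS and CDS/3'UTR
#' junctions.
#'
#' @param x a `metagene_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$density, type = "l",
                 xlab = "composite transcript position",
                 ylab = "peak density", ...)
  graphics::abline(v = x$boundaries, lty = 2, col = "grey40")
  invisible(x)
}
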