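# RRACH consensus motif analysis: top-N enriched regions, motif scanning,
# and a position frequency matrix over the matched 5-mers.
# RRACH: R = A/G, H = A/C/U; canonical instance GGACU.

RRACH_SETS <- list(c("A", "G"), c("A", "G"), "A", "C", c("A", "C", "T"))

#' Select the top-N most enriched regions
#'
#' The `n` highest-score peaks; ties are broken by (chrom, start). When
#' fewer than `n` peaks exist, all are returned with a warning.
#'
#' @param peaks a [peak_set()].
#' @param n number of regions to keep (default 1000).
#' @return A [peak_set()].
#' @export
top_regions <- function(peaks, n = 1000) {
  if (n < 1) stop("n must be >= 1")
  if (nrow(peaks) < n) {
    warning("only ", nrow(peaks), " peaks available (requested ", n, ")")
    n <- nrow(peaks)
  }
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  out <- peaks[ord[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(peaks)
  attr(out, "sample_key") <- attr(peaks, "sample_key")
  out
}

#' Scan a sequence for RRACH motifs
#'
#' Reports every offset (0-based) whose 5-mer matches R R A C H with
#' R = {A,G} and H = {A,C,T/U}; T and U are treated identically; N never
#' matches; overlapping matches are all reported.
#'
#' @param sequence nucleotide string over A,C,G,T,U,N (case-insensitive).
#' @return Data frame with columns `offset` (0-based) and `kmer`
#'   (DNA alphabet, T not U).
#' @export
scan_rrach <- function(sequence) {
  s <- chartr("u", "U", toupper(sequence))
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U", "N"))
  if (length(bad))
    stop("invalid nucleotide '", chars[bad[1]], "' at offset ", bad[1] - 1)
  chars[chars == "U"] <- "T"
  n <- length(chars)
  if (n < 5) return(data.frame(offset = integer(0), kmer = character(0)))
  ok <- rep(TRUE, n - 4)
  for (p in 1:5)
    ok <- ok & chars[p:(n - 5 + p)] %in% RRACH_SETS[[p]]
  offs <- which(ok) - 1L
  data.frame(offset = offs,
             kmer = vapply(offs, function(o)
               paste(chars[(o + 1):(o + 5)], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

#' Position frequency matrix of RRACH matches in enriched regions
#'
#' Extracts the genomic sequence of every region, orients it by the strand
#' of the gene the region is assigned to (reverse-complement for minus-strand
#' genes; regions not assignable to a gene are scanned on the plus strand
#' and counted), pools all RRACH matches across regions with equal weight,
#' and tabulates per-position nucleotide frequencies in the RNA alphabet.
#'
#' @param regions a [peak_set()] (e.g. from [top_regions()]).
#' @param genome a [Biostrings::DNAStringSet] of chromosome sequences.
#' @param models a `transcript_models` list, used for strand assignment.
#' @return Object of class `pfm`: `frequencies` (5 x 4 matrix, columns
#'   A,C,G,U; rows sum to 1 when `support > 0`), `support` (number of
#'   matched 5-mers), `n_unassigned` (regions scanned on + by default).
#' @export
build_pfm <- function(regions, genome, models) {
  alphabet <- c("A", "C", "G", "U")
  freq <- matrix(0, nrow = 5, ncol = 4,
                 dimnames = list(paste0("pos", 1:5), alphabet))
  if (nrow(regions) == 0)
    return(structure(list(frequencies = freq, support = 0L,
                          n_unassigned = 0L), class = "pfm"))
  asg <- assign_peaks(regions, models)
  strands <- vapply(asg$assignment, function(g)
    if (is.na(g)) "+" else models[[g]]$strand, character(1))
  counts <- freq
  support <- 0L
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
    clen <- Biostrings::width(genome[chrom])
    if (regions$end[i] > clen)
      stop("region beyond chromosome end: ", chrom, ":", regions$start[i],
           "-", regions$end[i])
    seq <- Biostrings::subseq(genome[[chrom]], regions$start[i] + 1,
                              regions$end[i])
    if (strands[i] == "-") seq <- Biostrings::reverseComplement(seq)
    hits <- scan_rrach(as.character(seq))
    if (!nrow(hits)) next
    support <- support + nrow(hits)
    km <- do.call(rbind, strsplit(hits$kmer, ""))
    km[km == "T"] <- "U"
    for (p in 1:5) {
      tb <- table(factor(km[, p], levels = alphabet))
      counts[p, ] <- counts[p, ] + as.integer(tb)
    }
  }
  if (support > 0) freq <- counts / support
  structure(list(frequencies = freq, support = support,
                 n_unassigned = sum(is.na(asg$assignment))),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> RRACH position frequency matrix, support = %d 5-mers\n",
              x$support))
  print(round(x$frequencies, 3))
  invisible(x)
}

#' Write a PFM as TSV and a transfac-style block
#'
#' @param pfm a `pfm` object.
#' @param path output TSV path; a transfac-style matrix block is written
#'   alongside with extension `.transfac`.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = 1:5, pfm$frequencies, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tf <- c("ID RRACH_m6A", "BF synthetic", "P0\tA\tC\tG\tU",
          sprintf("%02d\t%.0f\t%.0f\t%.0f\t%.0f", 1:5,
                  pfm$frequencies[, "A"] * pfm$support,
                  pfm$frequencies[, "C"] * pfm$support,
                  pfm$frequencies[, "G"] * pfm$support,
                  pfm$frequencies[, "U"] * pfm$support),
          "XX", "//")
  writeLines(tf, sub("\\.tsv$", ".transfac", path))
  invisible(path)
}
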