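#' @importFrom stats sd median cor rnorm runif rbinom rlnorm setNames phyper
#'   wilcox.test ks.test cor.test dhyper quantile
#' @importFrom utils read.table write.table head tail
NULL

# Internal coordinate convention: 0-based, half-open [start, end), as in BED.
# GTF is converted on read/write; BED passes through unchanged.

new_interval <- function(chrom, start, end, strand) {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Construct a transcript model
#'
#' A transcript model holds one gene's 5'UTR, CDS and 3'UTR intervals
#' (0-based, half-open genomic coordinates, all on one chromosome and strand)
#' and is the coordinate substrate for peak assignment and metagene profiling.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param utr5,cds,utr3 data frames with `start`/`end` columns (0-based,
#'   half-open), ordered by genomic position. `utr5`/`utr3` may have 0 rows;
#'   the CDS must have positive total length.
#' @return An object of class `transcript_model` with a `lengths` element
#'   giving the total nucleotide length of each region.
#' @export
transcript_model <- function(gene_id, chrom, strand, utr5, cds, utr3) {
  stopifnot(strand %in% c("+", "-"))
  regs <- list(utr5 = utr5, cds = cds, utr3 = utr3)
  for (nm in names(regs)) {
    r <- regs[[nm]]
    if (nrow(r) > 0 && any(r$start >= r$end))
      stop("invalid interval in region ", nm, " of gene ", gene_id)
  }
  lens <- vapply(regs, function(r) if (nrow(r)) sum(r$end - r$start) else 0L,
                 numeric(1))
  if (lens[["cds"]] <= 0) stop("gene ", gene_id, " has no CDS")
  # check pairwise non-overlap across all intervals
  all_iv <- do.call(rbind, lapply(regs, function(r) r[, c("start", "end")]))
  all_iv <- all_iv[order(all_iv$start), , drop = FALSE]
  if (nrow(all_iv) > 1 &&
      any(all_iv$start[-1] < all_iv$end[-nrow(all_iv)]))
    stop("overlapping intervals in gene ", gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 utr5 = utr5, cds = cds, utr3 = utr3, lengths = lens),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s:%d-%d (%s)  utr5=%dnt cds=%dnt utr3=%dnt\n",
              x$gene_id, x$chrom, tx_span(x)[1], tx_span(x)[2], x$strand,
              x$lengths[["utr5"]], x$lengths[["cds"]], x$lengths[["utr3"]]))
  invisible(x)
}

# genomic span of the transcript, c(start, end), 0-based half-open
tx_span <- function(model) {
  iv <- rbind(model$utr5, model$cds, model$utr3)
  c(min(iv$start), max(iv$end))
}

#' Read gene models from a GTF file
#'
#' Parses CDS / `five_prime_utr` / `three_prime_utr` feature rows (the
#' synonyms `5UTR`/`3UTR` are accepted), groups them by the `gene_id`
#' attribute and returns one [transcript_model] per gene. GTF 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention. Genes lacking any CDS row are skipped; the number skipped is
#' recorded in the `n_skipped` attribute and reported via a message.
#'
#' @param path path to a GTF file.
#' @return A named list of [transcript_model] objects
#'   (class `transcript_models`).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) stop("empty GTF file: ", path)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop("unparseable GTF line ", idx[which(nf != 9)[1]], " in ", path,
         " (expected 9 tab-separated fields)")
  m <- do.call(rbind, fields)
  type <- m[, 3]
  sel <- type %in% c("CDS", "five_prime_utr", "three_prime_utr", "5UTR", "3UTR")
  m <- m[sel, , drop = FALSE]
  lineno <- idx[sel]
  if (nrow(m) == 0) stop("GTF file contains no CDS/UTR features: ", path)
  start1 <- suppressWarnings(as.numeric(m[, 4]))
  end1 <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | start1 > end1)
  if (length(bad))
    stop("unparseable GTF line ", lineno[bad[1]], ": bad coordinates")
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", m[, 9])
  bad <- which(!grepl('gene_id "', m[, 9], fixed = TRUE))
  if (length(bad))
    stop("unparseable GTF line ", lineno[bad[1]], ": missing gene_id attribute")
  region <- c(CDS = "cds", five_prime_utr = "utr5", three_prime_utr = "utr3",
              `5UTR` = "utr5", `3UTR` = "utr3")[m[, 3]]
  tab <- data.frame(gene_id = gid, chrom = m[, 1], strand = m[, 7],
                    start = start1 - 1, end = end1, region = region,
                    stringsAsFactors = FALSE)
  models <- list()
  n_skipped <- 0L
  for (g in unique(tab$gene_id)) {
    gt <- tab[tab$gene_id == g, ]
    if (!any(gt$region == "cds")) { n_skipped <- n_skipped + 1L; next }
    if (length(unique(gt$chrom)) != 1 || length(unique(gt$strand)) != 1)
      stop("gene ", g, " mixes chromosomes or strands")
    reg <- function(r) {
      x <- gt[gt$region == r, c("start", "end")]
      x[order(x$start), , drop = FALSE]
    }
    models[[g]] <- transcript_model(g, gt$chrom[1], gt$strand[1],
                                    reg("utr5"), reg("cds"), reg("utr3"))
  }
  if (n_skipped > 0)
    message(n_skipped, " gene(s) without CDS skipped")
  structure(models, class = "transcript_models", n_skipped = n_skipped)
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("<transcript_models> %d genes (%d skipped on read)\n",
              length(x), attr(x, "n_skipped") %||% 0L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write gene models to a GTF file
#'
#' Emits `gene`, `five_prime_utr`, `CDS` and `three_prime_utr` rows with
#' 1-based inclusive coordinates, round-trippable by [read_gene_models()].
#'
#' @param models a `transcript_models` list.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  rows <- character(0)
  for (mdl in models) {
    span <- tx_span(mdl)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.1";',
                     mdl$gene_id, mdl$gene_id)
    rows <- c(rows, sprintf("%s\tm6avar\tgene\t%d\t%d\t.\t%s\t.\t%s",
                            mdl$chrom, span[1] + 1, span[2], mdl$strand, attrs))
    feats <- c(utr5 = "five_prime_utr", cds = "CDS", utr3 = "three_prime_utr")
    for (nm in names(feats)) {
      r <- mdl[[nm]]
      if (nrow(r) == 0) next
      rows <- c(rows, sprintf("%s\tm6avar\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              mdl$chrom, feats[[nm]], r$start + 1, r$end,
                              mdl$strand, attrs))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Construct a peak set
#'
#' A peak set is a data frame of scored genomic intervals (0-based half-open)
#' for one sample group and replicate.
#'
#' @param chrom,start,end,name,score,strand peak columns; `strand` defaults
#'   to `"."` (unstranded peak calls).
#' @param sample_key optional list with elements `tissue`, `condition`,
#'   `genotype`, `replicate` identifying the sample the peaks came from.
#' @return A data frame of class `peak_set`.
#' @export
peak_set <- function(chrom = character(0), start = integer(0),
                     end = integer(0), name = character(0),
                     score = numeric(0), strand = NULL, sample_key = NULL) {
  if (is.null(strand)) strand <- rep(".", length(chrom))
  if (length(start) && any(start >= end))
    stop("peak with start >= end: ",
         paste0(chrom[start >= end][1], ":", start[start >= end][1]))
  if (any(!is.finite(score))) stop("non-finite peak score")
  ps <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   score = score, strand = strand, stringsAsFactors = FALSE)
  class(ps) <- c("peak_set", "data.frame")
  attr(ps, "sample_key") <- sample_key
  ps
}

#' @export
print.peak_set <- function(x, ...) {
  key <- attr(x, "sample_key")
  keytxt <- if (is.null(key)) "" else
    sprintf(" [%s]", paste(unlist(key), collapse = "."))
  cat(sprintf("<peak_set> %d peaks%s\n", nrow(x), keytxt))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

#' Read m6A peak calls from a BED file
#'
#' Accepts BED5 or BED6 (chrom, start, end, name, score, and optionally
#' strand). BED's native 0-based half-open coordinates are preserved; the
#' score column is parsed as the peak score.
#'
#' @param path path to a BED file.
#' @param sample_key optional sample key, see [peak_set()].
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, sample_key = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1)) == 0)
    return(peak_set(sample_key = sample_key))
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(tab) < 5) stop("BED file needs >= 5 columns: ", path)
  start <- as.numeric(tab[[2]]); end <- as.numeric(tab[[3]])
  if (any(is.na(start) | is.na(end)))
    stop("non-numeric coordinate in BED record ",
         which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end in BED record ", bad[1], " (",
         tab[[1]][bad[1]], ":", tab[[2]][bad[1]], "-", tab[[3]][bad[1]], ")")
  score <- suppressWarnings(as.numeric(tab[[5]]))
  if (any(is.na(score)))
    stop("non-numeric score in BED record ", which(is.na(score))[1])
  strand <- if (ncol(tab) >= 6) tab[[6]] else rep(".", nrow(tab))
  peak_set(tab[[1]], start, end, tab[[4]], score, strand, sample_key)
}

#' Write a peak set to a BED file
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), peaks$name,
                   formatC(peaks$score, format = "g", digits = 15),
                   peaks$strand)
  writeLines(lines, path)
  invisible(path)
}

sample_key_fields <- c("tissue", "condition", "genotype", "fraction",
                       "replicate")

parse_sample_token <- function(token) {
  parts <- strsplit(token, ".", fixed = TRUE)[[1]]
  if (length(parts) != 5 || !grepl("^rep[0-9]+$", parts[5]))
    stop("malformed sample header token: '", token,
         "' (expected tissue.condition.genotype.fraction.repN)")
  list(tissue = parts[1], condition = parts[2], genotype = parts[3],
       fraction = parts[4], replicate = as.integer(sub("rep", "", parts[5])))
}

#' Construct an expression matrix
#'
#' Genes-by-samples matrix of nonnegative abundances (FPKM) with structured
#' sample metadata.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample
#'   tokens `tissue.condition.genotype.fraction.repN`.
#' @param samples optional data frame of sample metadata; derived from the
#'   column names when omitted.
#' @return An object of class `expression_matrix` with elements `values`
#'   (matrix), `samples` (data frame) and `genes` (character).
#' @export
expression_matrix <- function(values, samples = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene id: ",
         rownames(values)[duplicated(rownames(values))][1])
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0")
  if (is.null(samples)) {
    samples <- do.call(rbind, lapply(colnames(values), function(tok)
      as.data.frame(parse_sample_token(tok), stringsAsFactors = FALSE)))
  }
  if (anyDuplicated(samples)) stop("duplicated sample metadata tuple")
  structure(list(values = values, samples = samples,
                 genes = rownames(values)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$tissue, x$samples$fraction)
  print(tab)
  invisible(x)
}

#' @export
summary.expression_matrix <- function(object, ...) {
  cat(sprintf("expression_matrix: %d genes, %d samples\n",
              nrow(object$values), ncol(object$values)))
  cat("groups:\n")
  print(table(group_label(object$samples), object$samples$fraction))
  invisible(object)
}

# "tissue.condition.genotype" label per sample row
group_label <- function(samples) {
  paste(samples$tissue, samples$condition, samples$genotype, sep = ".")
}

#' Read an expression matrix from TSV
#'
#' The first column holds gene ids; remaining column headers encode sample
#' metadata as `tissue.condition.genotype.fraction.repN` tokens.
#'
#' @param path path to a TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    quote = "", stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("duplicated gene id: ", tab[[1]][duplicated(tab[[1]])][1])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(vals))) stop("non-numeric expression value")
  if (any(vals < 0))
    stop("negative expression value for gene ",
         tab[[1]][which(rowSums(vals < 0) > 0)[1]])
  rownames(vals) <- tab[[1]]
  expression_matrix(vals)
}

#' Write an expression matrix to TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  # 17 significant digits so values survive the text round trip exactly
  chars <- matrix(sprintf("%.17g", expr$values), nrow = nrow(expr$values))
  lines <- c(paste(c("gene", colnames(expr$values)), collapse = "\t"),
             paste(rownames(expr$values),
                   apply(chars, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Compute FPKM from raw counts
#'
#' FPKM = count * 1e9 / (gene length * library size): fragments per kilobase
#' of transcript per million mapped reads.
#'
#' @param counts nonnegative integer matrix (genes x samples).
#' @param lengths transcript length in nucleotides per gene (> 0).
#' @param library_sizes total mapped reads per sample (> 0).
#' @return An [expression_matrix()] of FPKM values (when `counts` carries the
#'   required dimnames), otherwise a bare matrix.
#' @export
compute_fpkm <- function(counts, lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("lengths must have one entry per gene")
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per sample")
  if (any(lengths <= 0)) stop("zero or negative gene length")
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  if (any(counts < 0)) stop("negative count")
  fpkm <- counts * 1e9 / outer(lengths, library_sizes)
  dimnames(fpkm) <- dimnames(counts)
  if (!is.null(rownames(fpkm)) && !is.null(colnames(fpkm)) &&
      all(grepl("\\.rep[0-9]+$", colnames(fpkm))))
    expression_matrix(fpkm)
  else fpkm
}

# subset an expression_matrix to sample rows selected by a predicate
subset_samples <- function(expr, sel) {
  expression_matrix(expr$values[, sel, drop = FALSE],
                    expr$samples[sel, , drop = FALSE])
}
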