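# Seeded synthetic-data generator. Emulates the study design: two tissues
# (leaf, flower) x two conditions (control CS, heat stress HS) x two
# genotypes (wild type, demethylase mutant), 3 input RNA-seq replicates and
# 2 m6A-RIP IP replicates per group. Plants (i) tissue-specific methylation
# (stronger in flower), (ii) a negative coupling between methylation and
# per-gene CV^2, (iii) flower-specific hypermethylation of a gene subset in
# the mutant, (iv) heat-induced genes whose induction is attenuated in
# flowers and further in mutant flowers, and (v) stop-codon-proximal peaks
# carrying an RRACH motif. Every generated quantity is recorded as ground
# truth, so downstream stages can be tested by parameter recovery.

SIM_TISSUES <- c("leaf", "flower")
SIM_CONDITIONS <- c("CS", "HS")
SIM_GENOTYPES <- c("wt", "mutant")

#' Simulation configuration
#'
#' Defaults describe the emulated study design; see the package vignette for
#' the rationale behind each value.
#'
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration.
#' @param n_genes number of single-transcript genes.
#' @param region_lengths mean nucleotide lengths of (utr5, cds, utr3);
#'   realized lengths are drawn around these (minimum 30 nt, CDS a multiple
#'   of 3).
#' @param n_input_reps,n_ip_reps replicates per sample group (3 RNA-seq
#'   input, 2 RIP IP).
#' @param frac_methylated probability that a gene is methylated in each
#'   tissue (flower > leaf).
#' @param coupling multiplicative reduction (< 1) of methylated genes'
#'   log-scale dispersion: the planted negative methylation-variability
#'   relation. 1 disables the effect.
#' @param mutant_shift log2 enrichment increase planted in mutant flowers
#'   for a subset of flower-methylated genes.
#' @param n_mutant_shifted size of that subset.
#' @param shift_coupling extra dispersion reduction applied to the shifted
#'   subset in mutant flowers (hypermethylated genes lose additional
#'   variability). 1 disables.
#' @param heat_genes number of heat-induced genes.
#' @param heat_induction log2 induction of heat genes in wild-type leaves
#'   under HS.
#' @param attenuation multiplicative factors on the log2 induction in
#'   (wt flower, mutant flower); leaves are unattenuated.
#' @param motif 5-mer planted at peak centers (DNA alphabet;
#'   default GGACT, the canonical RRACH instance GGACU).
#' @param peak_width,peak_center_sd peak width (nt) and the Gaussian sd of
#'   the peak center around the CDS/3'UTR boundary (nt).
#' @param replicate_specific_frac fraction of planted peak loci present in
#'   only one IP replicate (exercises the reproducibility filter).
#' @param score_jitter_sd sd (log2 units) of the jitter added to planted
#'   enrichment when emitting peak scores.
#' @param enrichment_range range of the planted log2 enrichment E for
#'   methylated genes (uniform draw).
#' @param mu_meanlog,mu_sdlog lognormal parameters of gene-level median
#'   FPKM.
#' @param sigma_meanlog,sigma_sdlog lognormal parameters of the per-gene
#'   log-scale replicate dispersion.
#' @param ip_sdlog log-scale dispersion of IP replicates.
#' @param aux_effect upward shift of flower-methylated genes' auxiliary
#'   (stress-granule style) scores. 0 disables.
#' @param spacer intergenic spacer (nt).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 2000,
                       region_lengths = c(utr5 = 150, cds = 900, utr3 = 300),
                       n_input_reps = 3,
                       n_ip_reps = 2,
                       frac_methylated = c(leaf = 0.3, flower = 0.6),
                       coupling = 0.3,
                       mutant_shift = 1.5,
                       n_mutant_shifted = 150,
                       shift_coupling = 0.5,
                       heat_genes = 200,
                       heat_induction = 3,
                       attenuation = c(wt_flower = 0.5, mutant_flower = 0.25),
                       motif = "GGACT",
                       peak_width = 100,
                       peak_center_sd = 50,
                       replicate_specific_frac = 0.1,
                       score_jitter_sd = 0.1,
                       enrichment_range = c(1, 4),
                       mu_meanlog = log(20),
                       mu_sdlog = 1,
                       sigma_meanlog = log(0.35),
                       sigma_sdlog = 0.35,
                       ip_sdlog = 0.15,
                       aux_effect = 1,
                       spacer = 200) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, n_ip_reps >= 1, heat_genes >= 0,
            length(region_lengths) == 3)
  if (n_input_reps < 2)
    stop("need at least 2 input replicates per group (CV^2 undefined)")
  if (any(frac_methylated < 0 | frac_methylated > 1))
    stop("frac_methylated must lie in [0, 1]")
  if (any(attenuation < 0 | attenuation > 1))
    stop("attenuation factors must lie in [0, 1]")
  if (replicate_specific_frac < 0 || replicate_specific_frac > 1)
    stop("replicate_specific_frac must lie in [0, 1]")
  if (nchar(motif) != 5 ||
      !all(strsplit(motif, "")[[1]] %in% c("A", "C", "G", "T")))
    stop("motif must be a 5-mer over A/C/G/T")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed=%d, %d genes, %d input + %d IP reps per group\n",
    x$seed, x$n_genes, x$n_input_reps, x$n_ip_reps))
  cat(sprintf("  frac_methylated leaf=%.2f flower=%.2f, coupling=%.2f\n",
              x$frac_methylated[["leaf"]], x$frac_methylated[["flower"]],
              x$coupling))
  invisible(x)
}

# all 8 sample groups in a fixed, deterministic order
sim_groups <- function() {
  g <- expand.grid(genotype = SIM_GENOTYPES, condition = SIM_CONDITIONS,
                   tissue = SIM_TISSUES, stringsAsFactors = FALSE)
  g[, c("tissue", "condition", "genotype")]
}

#' Generate the synthetic genome and gene models
#'
#' Lays `n_genes` single-transcript genes head-to-tail on one synthetic
#' chromosome with intergenic spacers. Region lengths are drawn around the
#' configured means (sd 20% of the mean, minimum 30 nt; CDS rounded to a
#' multiple of 3); strands are random; the sequence is uniform random over
#' A/C/G/T (motifs are planted later by [generate_peaks()]).
#'
#' @param config a [sim_config()].
#' @return List: `models` (a `transcript_models` list), `genome`
#'   (a [Biostrings::DNAStringSet] with one chromosome `chrS`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    rl <- config$region_lengths
    draw_len <- function(m) pmax(30, round(stats::rnorm(n, m, 0.2 * m)))
    l5 <- draw_len(rl[["utr5"]])
    lc <- pmax(30, 3 * round(draw_len(rl[["cds"]]) / 3))
    l3 <- draw_len(rl[["utr3"]])
    strand <- sample(c("+", "-"), n, replace = TRUE)
    total <- l5 + lc + l3
    starts <- config$spacer + cumsum(c(0, (total + config$spacer)[-n]))
    ids <- sprintf("g%04d", seq_len(n))
    models <- vector("list", n)
    for (i in seq_len(n)) {
      s <- starts[i]
      if (strand[i] == "+") {
        utr5 <- data.frame(start = s, end = s + l5[i])
        cds <- data.frame(start = s + l5[i], end = s + l5[i] + lc[i])
        utr3 <- data.frame(start = s + l5[i] + lc[i], end = s + total[i])
      } else {
        utr3 <- data.frame(start = s, end = s + l3[i])
        cds <- data.frame(start = s + l3[i], end = s + l3[i] + lc[i])
        utr5 <- data.frame(start = s + l3[i] + lc[i], end = s + total[i])
      }
      models[[i]] <- transcript_model(ids[i], "chrS", strand[i],
                                      utr5, cds, utr3)
    }
    names(models) <- ids
    class(models) <- "transcript_models"
    attr(models, "n_skipped") <- 0L
    chrlen <- starts[n] + total[n] + config$spacer
    seq <- paste(sample(c("A", "C", "G", "T"), chrlen, replace = TRUE),
                 collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(seq, "chrS"))
    list(models = models, genome = genome)
  })
}

#' Generate the synthetic expression matrix and ground truth
#'
#' For each gene and sample group, input-fraction replicate FPKMs are drawn
#' from a lognormal with gene-level median mu and log-scale dispersion
#' sigma. Methylated genes' sigma is multiplied by `coupling` (< 1),
#' planting the negative methylation-variability relation; mutant-shifted
#' genes additionally get `shift_coupling` in mutant flowers. Heat genes'
#' medians are multiplied by `2^(heat_induction * attenuation)` under HS.
#' IP-fraction abundance is the input median times `2^E`, with planted
#' enrichment E > 0 for methylated genes (plus `mutant_shift` in mutant
#' flowers for the shifted subset) and E = 0 otherwise.
#'
#' @param config a [sim_config()].
#' @param models gene models from [generate_genome()].
#' @return List: `expr` (an [expression_matrix()]) and `truth` (a list of
#'   class `ground_truth` with per-gene flags and planted parameters).
#' @export
generate_expression <- function(config, models) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n <- length(models)
    ids <- names(models)
    mu <- stats::rlnorm(n, config$mu_meanlog, config$mu_sdlog)
    sigma <- stats::rlnorm(n, config$sigma_meanlog, config$sigma_sdlog)
    meth <- list(
      leaf = stats::rbinom(n, 1, config$frac_methylated[["leaf"]]) == 1,
      flower = stats::rbinom(n, 1, config$frac_methylated[["flower"]]) == 1)
    er <- config$enrichment_range
    E <- list(leaf = stats::runif(n, er[1], er[2]) * meth$leaf,
              flower = stats::runif(n, er[1], er[2]) * meth$flower)
    heat_idx <- sample(n, min(config$heat_genes, n))
    heat <- seq_len(n) %in% heat_idx
    flower_meth_idx <- which(meth$flower)
    shifted_idx <- if (length(flower_meth_idx))
      sample(flower_meth_idx,
             min(config$n_mutant_shifted, length(flower_meth_idx)))
    else integer(0)
    shifted <- seq_len(n) %in% shifted_idx
    groups <- sim_groups()
    cols <- list()
    meta <- list()
    for (i in seq_len(nrow(groups))) {
      ti <- groups$tissue[i]; co <- groups$condition[i]
      ge <- groups$genotype[i]
      atten <- if (ti == "leaf") 1
      else config$attenuation[[paste0(ge, "_flower")]]
      mu_gs <- mu * 2^(config$heat_induction * atten * heat * (co == "HS"))
      sigma_gs <- sigma * ifelse(meth[[ti]], config$coupling, 1)
      if (ti == "flower" && ge == "mutant")
        sigma_gs[shifted] <- sigma_gs[shifted] * config$shift_coupling
      E_gs <- E[[ti]] +
        config$mutant_shift * (ti == "flower" & ge == "mutant" & shifted)
      for (r in seq_len(config$n_input_reps)) {
        tok <- sprintf("%s.%s.%s.input.rep%d", ti, co, ge, r)
        cols[[tok]] <- stats::rlnorm(n, log(mu_gs), sigma_gs)
      }
      for (r in seq_len(config$n_ip_reps)) {
        tok <- sprintf("%s.%s.%s.IP.rep%d", ti, co, ge, r)
        cols[[tok]] <- stats::rlnorm(n, log(mu_gs) + E_gs * log(2),
                                     config$ip_sdlog)
      }
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- ids
    truth <- structure(list(
      genes = data.frame(gene_id = ids, mu = mu, sigma = sigma,
                         methylated_leaf = meth$leaf,
                         methylated_flower = meth$flower,
                         E_leaf = E$leaf, E_flower = E$flower,
                         heat_induced = heat, mutant_shifted = shifted,
                         stringsAsFactors = FALSE),
      config = config), class = "ground_truth")
    list(expr = expression_matrix(vals), truth = truth)
  })
}

#' Planted enrichment for one sample group
#'
#' @param truth a `ground_truth` object.
#' @param group group label `"tissue.condition.genotype"`.
#' @return Named numeric vector of planted log2 enrichment per gene.
#' @export
truth_planted_enrichment <- function(truth, group) {
  parts <- strsplit(group, ".", fixed = TRUE)[[1]]
  ti <- parts[1]; ge <- parts[3]
  g <- truth$genes
  E <- if (ti == "leaf") g$E_leaf else g$E_flower
  if (ti == "flower" && ge == "mutant")
    E <- E + truth$config$mutant_shift * g$mutant_shifted
  stats::setNames(E, g$gene_id)
}

#' Generate m6A peak calls and plant the motif
#'
#' Each gene carries one methylation site: its center is drawn once from a
#' Gaussian around the CDS/3'UTR boundary (sd `peak_center_sd`, clipped to
#' the transcript) and the configured 5-mer is written into the genome
#' there, on the gene's strand. For every group in whose tissue the gene is
#' methylated, a `peak_width`-nt peak is emitted at that site per IP
#' replicate, scored with the planted enrichment plus log2-scale jitter. A
#' configured fraction of peak loci per group is made replicate-specific
#' (present in only one IP replicate) to exercise the reproducibility
#' filter.
#'
#' @param config a [sim_config()].
#' @param models gene models from [generate_genome()].
#' @param truth ground truth from [generate_expression()].
#' @param genome the genome from [generate_genome()] (returned modified:
#'   motif planting edits the sequence).
#' @return List: `peaks` (named list of [peak_set()]s, one per
#'   group x IP replicate, names `"<group>_rep<r>"`), `genome` (modified),
#'   `centers` (data frame of planted peak loci, also stored into
#'   `truth$peaks` in the returned `truth`).
#' @export
generate_peaks <- function(config, models, truth, genome) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    groups <- sim_groups()
    g <- truth$genes
    chars <- strsplit(as.character(genome[["chrS"]]), "")[[1]]
    motif_fwd <- strsplit(config$motif, "")[[1]]
    motif_rev <- strsplit(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(config$motif))), "")[[1]]
    half <- floor(config$peak_width / 2)
    n <- nrow(g)
    # one methylation site per gene, planted once in the genome
    site <- rep(NA_integer_, n)
    meth_any <- which(g$methylated_leaf | g$methylated_flower)
    for (j in meth_any) {
      mdl <- models[[g$gene_id[j]]]
      span <- tx_span(mdl)
      # CDS/3'UTR boundary: 3' end of the CDS in genomic coordinates
      b <- if (mdl$strand == "+") max(mdl$cds$end) else min(mdl$cds$start)
      ctr <- round(stats::rnorm(1, b, config$peak_center_sd))
      ctr <- max(span[1] + 2, min(span[2] - 3, ctr))
      site[j] <- ctr
      mseq <- if (mdl$strand == "+") motif_fwd else motif_rev
      chars[(ctr - 1):(ctr + 3)] <- mseq  # 1-based window on 0-based center
    }
    peaksets <- list()
    centers_all <- list()
    for (i in seq_len(nrow(groups))) {
      ti <- groups$tissue[i]; co <- groups$condition[i]
      ge <- groups$genotype[i]
      glab <- paste(ti, co, ge, sep = ".")
      meth_idx <- which(if (ti == "leaf") g$methylated_leaf
                        else g$methylated_flower)
      E_gs <- truth_planted_enrichment(truth, glab)
      gene_ids <- g$gene_id[meth_idx]
      centers <- site[meth_idx]
      rep_spec <- stats::runif(length(meth_idx)) <
        config$replicate_specific_frac
      which_rep <- ifelse(rep_spec,
                          sample(config$n_ip_reps, length(meth_idx),
                                 replace = TRUE), NA_integer_)
      for (r in seq_len(config$n_ip_reps)) {
        keep <- !rep_spec | which_rep == r
        sc <- E_gs[gene_ids[keep]] +
          stats::rnorm(sum(keep), 0, config$score_jitter_sd)
        peaksets[[paste0(glab, "_rep", r)]] <- peak_set(
          chrom = rep("chrS", sum(keep)),
          start = centers[keep] - half,
          end = centers[keep] - half + config$peak_width,
          name = sprintf("%s_%s_rep%d", gene_ids[keep], glab, r),
          score = as.numeric(sc),
          strand = rep(".", sum(keep)),
          sample_key = list(tissue = ti, condition = co, genotype = ge,
                            replicate = r))
      }
      centers_all[[glab]] <- data.frame(
        gene_id = gene_ids, group = glab, center = centers,
        replicate_specific = rep_spec, which_rep = which_rep,
        stringsAsFactors = FALSE)
    }
    genome2 <- Biostrings::DNAStringSet(stats::setNames(
      paste(chars, collapse = ""), "chrS"))
    centers_df <- do.call(rbind, centers_all)
    rownames(centers_df) <- NULL
    truth$peaks <- centers_df
    list(peaks = peaksets, genome = genome2, centers = centers_df,
         truth = truth)
  })
}

#' Generate auxiliary per-gene scores
#'
#' Emulates an external per-gene score table (e.g. stress-granule
#' enrichment): flower-methylated genes' scores are standard normal shifted
#' up by `aux_effect`; all other genes are standard normal.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [generate_expression()].
#' @return Named numeric vector of scores (one per gene).
#' @export
generate_aux_scores <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    g <- truth$genes
    stats::setNames(stats::rnorm(nrow(g)) +
                      config$aux_effect * g$methylated_flower,
                    g$gene_id)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Runs the whole generator and writes GTF, genome FASTA (motif-planted),
#' expression TSV, one BED per group x IP replicate, the auxiliary score
#' TSV and the ground-truth tables. All outputs are byte-identical across
#' runs with the same configuration.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with all generated objects and file paths.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(config)
  ge <- generate_expression(config, gen$models)
  pk <- generate_peaks(config, gen$models, ge$truth, gen$genome)
  aux <- generate_aux_scores(config, ge$truth)
  paths <- list(gtf = file.path(dir, "genes.gtf"),
                genome = file.path(dir, "genome.fa"),
                expression = file.path(dir, "expression.tsv"),
                aux_scores = file.path(dir, "aux_scores.tsv"),
                truth_genes = file.path(dir, "ground_truth_genes.tsv"),
                truth_peaks = file.path(dir, "ground_truth_peaks.tsv"))
  write_gtf(gen$models, paths$gtf)
  Biostrings::writeXStringSet(pk$genome, paths$genome)
  write_expression(ge$expr, paths$expression)
  write.table(data.frame(gene_id = names(aux), score = aux,
                         row.names = NULL),
              paths$aux_scores, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pk$truth$genes, paths$truth_genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pk$truth$peaks, paths$truth_peaks, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$peaks <- list()
  for (nm in names(pk$peaks)) {
    p <- file.path(dir, paste0("peaks_", nm, ".bed"))
    write_peaks(pk$peaks[[nm]], p)
    paths$peaks[[nm]] <- p
  }
  invisible(list(config = config, models = gen$models, genome = pk$genome,
                 expr = ge$expr, truth = pk$truth, peaks = pk$peaks,
                 aux_scores = aux, paths = paths))
}
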