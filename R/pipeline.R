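# End-to-end orchestration: validate a run configuration, execute every
# analysis stage in order (variability -> enrichment -> peaks -> metagene ->
# motif -> association -> heat response), write all tables under one output
# directory and produce a manifest plus a JSON run report. Re-running with
# the same configuration reproduces every output byte-identically.

#' Default pipeline parameters
#'
#' @return Named list of every tunable pipeline parameter with its default.
#' @export
default_params <- function() {
  list(pseudocount = 0.1,
       hvg_min = 5, lvg_max = -10, cv_scale = 1, min_fpkm = 1,
       fold_threshold = 2, selection_fold = 2,
       bins = 100, smoothing_sigma = 2,
       top_n = 1000,
       reference_group = "flower.CS.wt",
       motif_group = "leaf.CS.wt",
       score_alternative = "greater",
       variability_alternative = "less",
       seed = 1)
}

#' Load and validate a pipeline run configuration
#'
#' A configuration is a YAML file (or an equivalent list) with an `inputs`
#' block (paths to `gtf`, `genome`, `expression`, a `peaks` map of
#' `group: [rep1.bed, rep2.bed]`, and optionally `aux_scores`) and an
#' optional `params` block overriding [default_params()]. Validation is
#' fail-fast: every referenced path is checked before any stage runs.
#'
#' @param config path to a YAML file, or a list.
#' @return Validated configuration list of class `run_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$inputs)) stop("config lacks an 'inputs' block")
  inp <- config$inputs
  for (f in c("gtf", "genome", "expression")) {
    if (is.null(inp[[f]])) stop("config inputs lack '", f, "'")
    if (!file.exists(inp[[f]]))
      stop("config input path does not exist: ", inp[[f]])
  }
  if (is.null(inp$peaks) || !length(inp$peaks))
    stop("config inputs lack 'peaks'")
  for (g in names(inp$peaks))
    for (p in inp$peaks[[g]])
      if (!file.exists(p)) stop("config input path does not exist: ", p)
  if (!is.null(inp$aux_scores) && !file.exists(inp$aux_scores))
    stop("config input path does not exist: ", inp$aux_scores)
  params <- default_params()
  for (nm in names(config$params)) {
    if (!nm %in% names(params)) stop("unknown parameter: ", nm)
    params[[nm]] <- config$params[[nm]]
  }
  structure(list(inputs = inp, params = params), class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes all stages on the configured inputs and writes every output
#' table, a `manifest.tsv` (file, md5 checksum) and a `report.json`
#' aggregating parameters, seeds, input checksums and headline statistics.
#' Any stage error is re-raised with the stage name after writing a
#' `FAILED` marker into the output directory.
#'
#' @param config a `run_config`, a list, or a YAML path
#'   (see [load_run_config()]).
#' @param outdir output directory (created; existing files overwritten).
#' @return Invisibly, the run report list.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "run_config")) config
  else load_run_config(config)
  p <- cfg$params
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  cat("m6avar pipeline run\n", file = log_path)
  logmsg <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, code) {
    logmsg(name, "started")
    tryCatch(code, error = function(e) {
      writeLines(paste0("FAILED at stage ", name, ": ",
                        conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  report <- list(parameters = p,
                 inputs = lapply(cfg$inputs, function(x)
                   if (is.character(x)) unname(tools::md5sum(x)) else
                     lapply(x, function(y) unname(tools::md5sum(y)))))
  outputs <- character(0)
  keep <- function(path) { outputs <<- c(outputs, path); path }

  inputs <- stage("load", {
    models <- read_gene_models(cfg$inputs$gtf)
    genome <- Biostrings::readDNAStringSet(cfg$inputs$genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    expr <- read_expression(cfg$inputs$expression)
    peaks <- lapply(cfg$inputs$peaks, function(beds) lapply(beds, read_peaks))
    aux <- if (!is.null(cfg$inputs$aux_scores)) {
      at <- read.table(cfg$inputs$aux_scores, header = TRUE, sep = "\t")
      stats::setNames(at[[2]], at[[1]])
    }
    list(models = models, genome = genome, expr = expr, peaks = peaks,
         aux = aux)
  })

  thr <- variability_thresholds(p$hvg_min, p$lvg_max, p$cv_scale)
  vt <- stage("variability", {
    vt <- variability_table(inputs$expr, thr, p$min_fpkm)
    keep(write_tsv(as.data.frame(vt), file.path(outdir, "variability.tsv")))
    keep(write_tsv(attr(vt, "counts"),
                   file.path(outdir, "variability_counts.tsv")))
    vt
  })

  enr <- stage("enrichment", {
    enr <- enrichment_table(inputs$expr, p$pseudocount)
    keep(write_tsv(as.data.frame(enr), file.path(outdir, "enrichment.tsv")))
    enr
  })

  rp <- stage("peaks", {
    rp <- list()
    asg_rows <- list()
    for (g in names(inputs$peaks)) {
      reps <- inputs$peaks[[g]]
      merged <- if (length(reps) >= 2)
        reproducible_peaks(reps[[1]], reps[[2]]) else reps[[1]]
      rp[[g]] <- merged
      keep(write_peaks(merged,
                       file.path(outdir, paste0("peaks_reproducible_", g,
                                                ".bed"))))
      asg <- assign_peaks(merged, inputs$models)
      asg_rows[[g]] <- data.frame(gene_id = names(asg$counts), group = g,
                                  peak_count = as.integer(asg$counts))
      logmsg("peaks", g, ": ", nrow(merged), " reproducible, ",
             asg$n_unassigned, " unassigned")
    }
    keep(write_tsv(do.call(rbind, asg_rows),
                   file.path(outdir, "peak_counts.tsv")))
    rp
  })

  profiles <- stage("metagene", {
    profs <- list()
    tab <- NULL
    for (g in names(rp)) {
      pr <- metagene_density(rp[[g]], inputs$models, p$bins,
                             p$smoothing_sigma)
      profs[[g]] <- pr
      tab <- if (is.null(tab))
        data.frame(bin_center = pr$bin_centers, pr$density,
                   check.names = FALSE)
      else cbind(tab, pr$density)
      names(tab)[ncol(tab)] <- g
    }
    keep(write_tsv(tab, file.path(outdir, "metagene.tsv")))
    profs
  })

  pfm <- stage("motif", {
    mg <- p$motif_group
    if (!mg %in% names(rp)) stop("motif_group has no peaks: ", mg)
    top <- top_regions(rp[[mg]], p$top_n)
    pfm <- build_pfm(top, inputs$genome, inputs$models)
    keep(write_pfm(pfm, file.path(outdir, "motif_pfm.tsv")))
    keep(file.path(outdir, "motif_pfm.transfac"))
    pfm
  })

  assoc <- stage("association", {
    rg <- p$reference_group
    vrec <- vt[vt$group == rg, ]
    if (!nrow(vrec)) stop("reference_group absent: ", rg)
    qt <- variability_quartiles(vrec)
    meth <- call_methylated(enr, group = rg)
    qf <- fraction_methylated_by_quartile(qt, meth)
    keep(write_tsv(as.data.frame(qf),
                   file.path(outdir, "quartile_fractions.tsv")))
    res <- list(quartile_fractions = qf$fraction,
                quartile_monotone = attr(qf, "monotone"))
    # differential enrichment, mutant vs wt, per tissue (CS condition)
    for (ti in c("leaf", "flower")) {
      wt_g <- paste(ti, "CS", "wt", sep = ".")
      mu_g <- paste(ti, "CS", "mutant", sep = ".")
      if (!all(c(wt_g, mu_g) %in% enr$group)) next
      de <- differential_enrichment(enr[enr$group == wt_g, ],
                                    enr[enr$group == mu_g, ],
                                    p$fold_threshold)
      keep(write_tsv(de, file.path(outdir,
                                   paste0("differential_", ti, ".tsv"))))
      res[[paste0("n_regulated_", ti)]] <- sum(de$regulated)
      if (ti == "flower" && sum(de$regulated) >= 3) {
        dvar <- variability_difference(inputs$expr, wt_g, mu_g, thr)
        reg <- intersect(de$gene_id[de$regulated], names(dvar))
        if (length(reg) >= 3 && length(reg) <= length(dvar) / 2) {
          sc <- score_comparison(reg, dvar,
                                 alternative = p$variability_alternative,
                                 seed = p$seed)
          res$variability_shift_p <- sc$p_value
        }
      }
    }
    if (!is.null(inputs$aux)) {
      lvg <- unique(vrec$gene_id[vrec$class == "LVG"])
      lvg <- intersect(lvg, names(inputs$aux))
      if (length(lvg) >= 3 && length(lvg) <= length(inputs$aux) / 2) {
        sc <- score_comparison(lvg, inputs$aux,
                               alternative = p$score_alternative,
                               seed = p$seed)
        res$aux_score_p <- sc$p_value
      }
    }
    res
  })

  heat <- stage("heat", {
    hm <- heat_response_matrix(inputs$expr, p$selection_fold, p$pseudocount)
    keep(write_tsv(data.frame(gene_id = rownames(hm$values), hm$values,
                              check.names = FALSE),
                   file.path(outdir, "heat_response.tsv")))
    hm
  })

  report$statistics <- c(assoc, list(
    heat_fc_column_means = as.list(heat$column_means),
    n_heat_activated = nrow(heat$values),
    motif_support = pfm$support,
    metagene_argmax = lapply(profiles, function(pr)
      pr$bin_centers[which.max(pr$density)])))
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- c(outputs, report_path)
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)))
  manifest <- manifest[order(manifest$file), ]
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  logmsg("done", length(outputs), " outputs written")
  invisible(report)
}
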