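# Shared fixtures and independent oracles. Fixtures are generated in code
# and cached per test run; oracles are deliberately naive re-implementations
# used only to check the package's fast paths.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the default study-scale fixture: 2000 genes, all effects planted
default_fixture <- function() {
  cache_fixture("default", function() {
    cfg <- sim_config(seed = 1)
    gen <- generate_genome(cfg)
    ge <- generate_expression(cfg, gen$models)
    pk <- generate_peaks(cfg, gen$models, ge$truth, gen$genome)
    aux <- generate_aux_scores(cfg, ge$truth)
    list(config = cfg, models = gen$models, genome = pk$genome,
         expr = ge$expr, truth = pk$truth, peaks = pk$peaks, aux = aux)
  })
}

# a quick fixture for integration tests
small_fixture <- function() {
  cache_fixture("small", function() {
    cfg <- sim_config(seed = 7, n_genes = 120, heat_genes = 25,
                      n_mutant_shifted = 20)
    dir <- file.path(tempdir(), "m6avar_small_fixture")
    simulate_dataset(cfg, dir)
  })
}

# classification thresholds matched to the generator's dispersion design
# (unmethylated log2CV^2 around -3, methylated around -6.5)
fixture_thresholds <- function() variability_thresholds(-2, -6)

# hand-built three-region transcript: utr5 [0,100), cds [100,300),
# utr3 [300,400) on "+"; the minus-strand twin has the regions mirrored
toy_model <- function(strand = "+") {
  if (strand == "+")
    transcript_model("toy", "chr1", "+",
                     utr5 = data.frame(start = 0, end = 100),
                     cds = data.frame(start = 100, end = 300),
                     utr3 = data.frame(start = 300, end = 400))
  else
    transcript_model("toy", "chr1", "-",
                     utr3 = data.frame(start = 0, end = 100),
                     cds = data.frame(start = 100, end = 300),
                     utr5 = data.frame(start = 300, end = 400))
}

# expression matrix from a plain list: values[[group]] = genes x reps
make_expr <- function(groups, genes) {
  cols <- list()
  for (g in names(groups)) {
    m <- groups[[g]]
    for (r in seq_len(ncol(m)))
      cols[[paste0(g, ".rep", r)]] <- m[, r]
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- genes
  expression_matrix(vals)
}

# ---- independent oracles -------------------------------------------------

# quartile assignment by explicit sorting
oracle_quartiles <- function(gene_id, log2cv2) {
  ok <- !is.na(log2cv2)
  gene_id <- gene_id[ok]; log2cv2 <- log2cv2[ok]
  n <- length(gene_id)
  ord <- order(log2cv2, gene_id)
  bounds <- floor(n * (1:4) / 4)  # cumulative quartile sizes, differ by <= 1
  qs <- character(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)
    qs[i] <- paste0("Q", which(bounds >= rank_i)[1])
  }
  stats::setNames(qs, gene_id)
}

# exhaustive permutation null for the rank-sum test (no ties assumed)
oracle_rank_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(length(pooled), nx)
  sums <- apply(sets, 2, function(idx) sum(r[idx]))
  if (alternative == "less") mean(sums <= obs) else mean(sums >= obs)
}

# hypergeometric upper tail by direct summation over choose()
oracle_hyper_p <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# top-n selection by full sort
oracle_topn <- function(peaks, n) {
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
}

# RRACH scan by regular expression (overlapping via lookahead)
oracle_scan_offsets <- function(seq) {
  s <- gsub("U", "T", toupper(seq))
  m <- gregexpr("(?=[AG][AG]AC[ACT])", s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}
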