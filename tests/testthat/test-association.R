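# Rank tests, hypergeometric overlaps, quartile fractions, score
# comparisons and the heat-response matrix.

test_that("quartile methylated fractions are counted correctly", {
  q <- factor(rep(paste0("Q", 1:4), each = 2), levels = paste0("Q", 1:4))
  names(q) <- paste0("g", 1:8)
  qf <- fraction_methylated_by_quartile(q, c("g1", "g2", "g3"))
  expect_equal(qf$fraction, c(1, 0.5, 0, 0))
  expect_true(attr(qf, "monotone"))
  expect_equal(fraction_methylated_by_quartile(q, character(0))$fraction,
               rep(0, 4))
  expect_equal(fraction_methylated_by_quartile(q, names(q))$fraction,
               rep(1, 4))
  empty_q <- factor(rep("Q1", 4), levels = paste0("Q", 1:4))
  names(empty_q) <- paste0("g", 1:4)
  expect_error(fraction_methylated_by_quartile(empty_q, "g1"), "empty")
})

test_that("the rank test matches exact small-sample theory", {
  r <- rank_test_one_tailed(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(r$p_value, 1 / 20)  # one extreme split of C(6,3) = 20
  expect_true(r$exact)
  # swapping the samples flips the alternative and preserves p
  r2 <- rank_test_one_tailed(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(r2$p_value, r$p_value)
  # identical large samples: p about one half
  set.seed(71)
  x <- rnorm(300)
  r3 <- rank_test_one_tailed(x, x, "less")
  expect_equal(r3$p_value, 0.5, tolerance = 0.01)
  expect_false(r3$exact)
  expect_error(rank_test_one_tailed(numeric(0), 1, "less"), "empty")
})

test_that("the exact branch agrees with exhaustive permutation enumeration", {
  set.seed(72)
  for (i in 1:250) {
    nx <- sample(1:4, 1); ny <- sample(1:4, 1)
    v <- sample(1000, nx + ny) / 7  # distinct: no ties
    x <- v[seq_len(nx)]; y <- v[nx + seq_len(ny)]
    alt <- sample(c("less", "greater"), 1)
    mine <- rank_test_one_tailed(x, y, alt)$p_value
    expect_equal(mine, oracle_rank_p(x, y, alt), tolerance = 1e-10)
  }
})

test_that("hypergeometric overlap matches direct summation", {
  u <- paste0("g", 1:10)
  res <- set_overlap_test(u[1:5], u[1:5], u)
  expect_equal(res$p_value, 1 / 252)  # C(5,5)C(5,0)/C(10,5)
  expect_equal(res$overlap, 5)
  expect_equal(res$fold_enrichment, 2)
  # disjoint small sets in a large universe: p near 1
  big <- paste0("g", 1:1000)
  expect_gt(set_overlap_test(big[1:5], big[6:10], big)$p_value, 0.97)
  # A = universe: overlap = |B| with certainty
  expect_equal(set_overlap_test(u, u[1:3], u)$p_value, 1)
  expect_error(set_overlap_test(c(u, "zz"), u[1:3], u), "set_a")
  set.seed(73)
  for (i in 1:300) {
    N <- sample(5:50, 1)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    universe <- paste0("x", seq_len(N))
    a <- sample(universe, K); b <- sample(universe, n)
    res <- set_overlap_test(a, b, universe)
    expect_equal(res$p_value,
                 oracle_hyper_p(res$overlap, K, N, n), tolerance = 1e-12)
  }
})

test_that("fold-change correlation behaves on exact and null inputs", {
  set.seed(74)
  x <- rnorm(50); noise_free <- 2 * x + 1
  expect_equal(cor(x, noise_free), 1)
  expect_equal(cor(x, -x), -1)
  # null fixture: independent planted FC and enrichment change; replicate
  # dispersion kept low because shared input noise enters both quantities
  # with opposite sign and would otherwise couple them mechanically
  cfg <- sim_config(seed = 9, n_genes = 600, heat_genes = 120,
                    coupling = 1, sigma_meanlog = log(0.02),
                    sigma_sdlog = 0.1)
  gen <- generate_genome(cfg)
  ge <- generate_expression(cfg, gen$models)
  res <- fc_correlation(ge$expr)
  expect_equal(nrow(res), 4)  # one contrast per tissue x genotype
  expect_true(all(abs(res$r) < 0.1))
  expect_true(all(res$n > 500))
})

test_that("score_comparison is seeded, size-matched and calibrated", {
  set.seed(75)
  scores <- stats::setNames(rnorm(400), paste0("g", 1:400))
  gs <- paste0("g", 1:50)
  a <- score_comparison(gs, scores, "greater", seed = 10)
  b <- score_comparison(gs, scores, "greater", seed = 10)
  expect_identical(a$random_draws, b$random_draws)
  expect_identical(a$p_value, b$p_value)
  expect_length(a$random_draws[[1]], 50)
  expect_length(intersect(a$random_draws[[1]], gs), 0)
  expect_error(score_comparison(paste0("g", 1:300), scores, "greater"),
               "size-match")
  # null calibration: identical score distribution for all genes
  ps <- vapply(1:200, function(s) {
    sc <- stats::setNames(rnorm(120), paste0("h", 1:120))
    score_comparison(paste0("h", 1:30), sc, "greater", seed = s)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.05)
  # planted effect: recovered at the default seed
  cfg <- sim_config(seed = 12, n_genes = 500, aux_effect = 1)
  gen <- generate_genome(cfg)
  ge <- generate_expression(cfg, gen$models)
  aux <- generate_aux_scores(cfg, ge$truth)
  meth <- ge$truth$genes$gene_id[ge$truth$genes$methylated_flower]
  meth <- meth[seq_len(min(length(meth), 200))]
  expect_lt(score_comparison(meth, aux, "greater", seed = 1)$p_value, 0.05)
})

test_that("heat-response selection is inclusive and ordered by attenuation", {
  # hand-built: gene hA has exactly two-fold induction in wt leaf
  pc <- 0.1
  base <- 10
  hs_exact <- 2 * (base + pc) - pc  # makes (hs+pc)/(cs+pc) exactly 2
  groups <- list()
  for (g in c("leaf.CS.wt.input", "leaf.HS.wt.input",
              "flower.CS.wt.input", "flower.HS.wt.input",
              "leaf.CS.mutant.input", "leaf.HS.mutant.input",
              "flower.CS.mutant.input", "flower.HS.mutant.input"))
    groups[[g]] <- cbind(c(base, base), c(base, base))
  groups[["leaf.HS.wt.input"]] <- cbind(c(hs_exact, base), c(hs_exact, base))
  ex <- make_expr(groups, c("hA", "hB"))
  hm <- heat_response_matrix(ex, selection_fold = 2, pseudocount = pc)
  expect_equal(rownames(hm$values), "hA")  # boundary gene included
  expect_equal(unname(hm$values["hA", "wt.leaf"]), 1)
  expect_equal(colnames(hm$values),
               c("wt.leaf", "wt.flower", "mutant.leaf", "mutant.flower"))
  # nothing passes: empty matrix with a warning
  groups[["leaf.HS.wt.input"]] <- cbind(c(base, base), c(base, base))
  expect_warning(h0 <- heat_response_matrix(make_expr(groups, c("hA", "hB"))),
                 "no gene")
  expect_equal(nrow(h0$values), 0)
  # fixture: attenuation ordering recovered in the column means
  fx <- default_fixture()
  hm <- heat_response_matrix(fx$expr)
  cm <- hm$column_means
  expect_gt(cm[["wt.leaf"]], cm[["wt.flower"]])
  expect_gt(cm[["wt.flower"]], cm[["mutant.flower"]])
})
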