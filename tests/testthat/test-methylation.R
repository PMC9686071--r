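# Enrichment scoring, methylation calls, reproducible peaks, assignment and
# differential enrichment.

test_that("enrichment_score matches hand evaluations", {
  expect_equal(enrichment_score(4, 1, pseudocount = 0), 2)
  expect_equal(enrichment_score(c(3, 5), c(1, 1), pseudocount = 0), 2)
  expect_equal(enrichment_score(2, 2, pseudocount = 0), 0)
  expect_equal(enrichment_score(0, 1, pseudocount = 0.1), log2(0.1 / 1.1))
  expect_equal(round(enrichment_score(0, 1, pseudocount = 0.1), 3), -3.459)
  expect_true(is.na(enrichment_score(0, 0, pseudocount = 0)))
  expect_error(enrichment_score(1, 1, pseudocount = -1), "pseudocount")
  expect_error(enrichment_score(numeric(0), 1), "empty")
})

test_that("enrichment_score is antisymmetric in IP and input", {
  set.seed(41)
  for (i in 1:100) {
    ip <- runif(3, 0, 20); inp <- runif(2, 0, 20)
    expect_equal(enrichment_score(ip, inp), -enrichment_score(inp, ip))
  }
})

test_that("methylation calls use a strict threshold", {
  recs <- data.frame(gene_id = c("a", "b", "c"), group = "leaf.CS.wt",
                     enrichment = c(0.5, 0, -1))
  expect_equal(call_methylated(recs), "a",
               ignore_attr = TRUE)   # 0 excluded: strictly > 0
  expect_equal(attr(call_methylated(recs), "counts")$n_methylated, 1)
  expect_equal(call_methylated(recs, threshold = -2), c("a", "b", "c"),
               ignore_attr = TRUE)
})

test_that("reproducible_peaks merges by the stated rule", {
  k <- function(r) list(tissue = "leaf", condition = "CS", genotype = "wt",
                        replicate = r)
  r1 <- peak_set("chr1", 100, 150, "p1", 10, ".", sample_key = k(1))
  r2 <- peak_set("chr1", 140, 200, "q1", 20, ".", sample_key = k(2))
  m <- reproducible_peaks(r1, r2)
  expect_equal(m$start, 100)
  expect_equal(m$end, 200)
  expect_equal(m$score, 15)
  # identical replicates: idempotent, coordinates and scores preserved
  set.seed(42)
  starts <- sort(sample(1e5, 50)) * 10
  ps <- peak_set(rep("chr1", 50), starts, starts + 100,
                 paste0("p", 1:50), runif(50, 1, 9), sample_key = k(1))
  m2 <- reproducible_peaks(ps, ps)
  expect_equal(m2$start, ps$start)
  expect_equal(m2$end, ps$end)
  expect_equal(m2$score, ps$score)
  # disjoint sets: empty result; output never exceeds |rep1|
  far <- peak_set("chr1", 1e7, 1e7 + 50, "z", 1, ".", sample_key = k(2))
  expect_equal(nrow(reproducible_peaks(ps, far)), 0)
  expect_lte(nrow(reproducible_peaks(ps, r2)), nrow(ps))
  # group-key mismatch is an error
  kf <- list(tissue = "flower", condition = "CS", genotype = "wt",
             replicate = 2)
  expect_error(reproducible_peaks(
    r1, peak_set("chr1", 140, 200, "q", 1, ".", sample_key = kf)),
    "different groups")
})

test_that("peak assignment uses midpoints with overlap tie-breaking", {
  models <- list(
    gA = transcript_model("gA", "chr1", "+",
                          data.frame(start = 0, end = 50),
                          data.frame(start = 50, end = 500),
                          data.frame(start = 500, end = 600)),
    gB = transcript_model("gB", "chr1", "+",
                          data.frame(start = 2000, end = 2050),
                          data.frame(start = 2050, end = 2500),
                          data.frame(start = 2500, end = 2600)))
  class(models) <- "transcript_models"
  ps <- peak_set(rep("chr1", 3), c(100, 2100, 5000),
                 c(200, 2200, 5100), paste0("p", 1:3), 1:3)
  asg <- assign_peaks(ps, models)
  expect_equal(asg$assignment, c("gA", "gB", NA))
  expect_equal(asg$n_unassigned, 1)
  expect_equal(unname(asg$counts), c(1L, 1L))
  expect_equal(sum(asg$counts) + asg$n_unassigned, nrow(ps))

  # overlapping genes: larger overlap wins, then lexicographic id
  ov <- list(
    gY = transcript_model("gY", "chr1", "+",
                          data.frame(start = 0, end = 10),
                          data.frame(start = 10, end = 150),
                          data.frame(start = 150, end = 160)),
    gX = transcript_model("gX", "chr1", "+",
                          data.frame(start = 90, end = 100),
                          data.frame(start = 100, end = 400),
                          data.frame(start = 400, end = 410)))
  class(ov) <- "transcript_models"
  # midpoint 125 in both; peak [50,200) overlaps gY by 110, gX by 110 -> tie
  tie <- peak_set("chr1", 50, 200, "t", 1)
  expect_equal(assign_peaks(tie, ov)$assignment, "gX")
  # peak [100,200): overlaps gY by 60, gX by 100 -> gX wins on overlap
  p2 <- peak_set("chr1", 100, 200, "t", 1)
  expect_equal(assign_peaks(p2, ov)$assignment, "gX")
  # peak [60,180): overlaps gY by 100, gX by 90 -> gY wins
  p3 <- peak_set("chr1", 60, 180, "t", 1)
  expect_equal(assign_peaks(p3, ov)$assignment, "gY")
})

test_that("differential enrichment flags at-least-two-fold gains inclusively", {
  wt <- data.frame(gene_id = c("a", "b", "c"), enrichment = c(1, 1, NA))
  mu <- data.frame(gene_id = c("a", "b", "c"), enrichment = c(2, 1.9, 5))
  de <- differential_enrichment(wt, mu, fold_threshold = 2)
  expect_equal(de$gene_id, c("a", "b"))
  expect_equal(de$regulated, c(TRUE, FALSE))  # delta 1.0 in, 0.9 out
  expect_equal(attr(de, "n_dropped"), 1)
  expect_error(differential_enrichment(
    wt, data.frame(gene_id = "z", enrichment = 1)), "disjoint")
  expect_error(differential_enrichment(wt, mu, fold_threshold = 1))
})

test_that("planted enrichment is recovered from the synthetic fixture", {
  fx <- default_fixture()
  enr <- enrichment_table(fx$expr)
  grp <- "flower.CS.wt"
  E <- truth_planted_enrichment(fx$truth, grp)
  e <- enr$enrichment[enr$group == grp]
  expect_gt(cor(E, e, method = "spearman"), 0.95)
  # mutant-shift recovery: flagged in flower, not in leaf
  sh <- fx$truth$genes$gene_id[fx$truth$genes$mutant_shifted]
  de_f <- differential_enrichment(enr[enr$group == "flower.CS.wt", ],
                                  enr[enr$group == "flower.CS.mutant", ])
  de_l <- differential_enrichment(enr[enr$group == "leaf.CS.wt", ],
                                  enr[enr$group == "leaf.CS.mutant", ])
  expect_gte(mean(de_f$regulated[de_f$gene_id %in% sh]), 0.9)
  expect_lt(mean(de_l$regulated[de_l$gene_id %in% sh]), 0.1)
})
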