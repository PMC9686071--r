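# Composite transcript coordinates and metagene density profiles.

test_that("composite positions respect region boundaries and strand", {
  plus <- toy_model("+")
  # first CDS base lands exactly on the utr5/cds junction
  expect_equal(composite_position(100, plus)$composite, 0.25)
  expect_equal(composite_position(100, plus)$region, "cds")
  # first base of the transcript
  expect_equal(composite_position(0, plus)$composite, 0)
  # last base approaches but never reaches 1
  last <- composite_position(399, plus)
  expect_lt(last$composite, 1)
  expect_gt(last$composite, 0.99)
  # first base of 3'UTR lands on the cds/utr3 junction
  expect_equal(composite_position(300, plus)$composite, 0.75)

  minus <- toy_model("-")
  # genomically-last base is the transcript start on the minus strand
  expect_equal(composite_position(399, minus)$composite, 0)
  expect_equal(composite_position(399, minus)$region, "utr5")
  # genomically-first base is the transcript end
  expect_gt(composite_position(0, minus)$composite, 0.99)
  # last CDS base (genomic start of the CDS) is just before the
  # cds/utr3 junction on the minus strand
  cp <- composite_position(100, minus)
  expect_equal(cp$region, "cds")
  expect_equal(cp$relative, 199 / 200)
  expect_error(composite_position(400, plus), "outside")
  expect_error(composite_position(50, plus,
                                  widths = c(0.3, 0.3, 0.3)), "sum to 1")
})

test_that("positions in annotation gaps snap to the nearest region edge", {
  gap <- transcript_model("gap", "chr1", "+",
                          utr5 = data.frame(start = 0, end = 100),
                          cds = data.frame(start = 200, end = 400),
                          utr3 = data.frame(start = 400, end = 500))
  near5 <- composite_position(120, gap)   # closer to utr5 end (99)
  expect_equal(near5$region, "utr5")
  expect_equal(near5$relative, 99 / 100)
  near_cds <- composite_position(180, gap)  # closer to cds start (200)
  expect_equal(near_cds$region, "cds")
  expect_equal(near_cds$composite, 0.25)
})

test_that("metagene density concentrates where the peaks are planted", {
  models <- list(toy = toy_model("+"))
  class(models) <- "transcript_models"
  # all peaks centered on the cds/utr3 boundary (composite 0.75)
  ps <- peak_set(rep("chr1", 20), rep(250, 20), rep(350, 20),
                 paste0("p", 1:20), runif(20))
  pr <- metagene_density(ps, models, bins = 100, smoothing_sigma = 2)
  expect_equal(pr$n_peaks, 20L)
  argmax <- pr$bin_centers[which.max(pr$density)]
  expect_lt(abs(argmax - 0.755), 0.0051)  # the bin containing 0.75
  # unit area
  expect_equal(sum(pr$density) * diff(pr$bin_edges[1:2]), 1,
               tolerance = 1e-9)
  # empty input: zero profile with a warning
  expect_warning(z <- metagene_density(peak_set(), models), "empty")
  expect_equal(z$density, rep(0, 100))
  expect_equal(z$n_peaks, 0L)
})

test_that("near-uniform peak placement yields a near-flat profile", {
  set.seed(55)
  models <- list(toy = toy_model("+"))
  class(models) <- "transcript_models"
  # composite-uniform sampling: draw the composite coordinate uniformly and
  # map it back to a genomic midpoint within the right region
  n <- 4000
  u <- runif(n)
  mids <- integer(n)
  for (i in seq_len(n)) {
    if (u[i] < 0.25) mids[i] <- floor(u[i] / 0.25 * 100)
    else if (u[i] < 0.75) mids[i] <- 100 + floor((u[i] - 0.25) / 0.5 * 200)
    else mids[i] <- 300 + floor((u[i] - 0.75) / 0.25 * 100)
  }
  ps <- peak_set(rep("chr1", n), pmax(0, mids - 5), mids + 6,
                 paste0("p", 1:n), runif(n))
  pr <- metagene_density(ps, models, bins = 50, smoothing_sigma = 2)
  expect_lt(max(pr$density) / min(pr$density), 2)
})

test_that("profiles are invariant under genome mirroring", {
  # mirror a plus-strand fixture: reverse-complement coordinates, flip
  # strand; odd peak width keeps midpoints exactly mirrored
  L <- 1000
  plus <- list(g1 = transcript_model("g1", "chr1", "+",
                                     data.frame(start = 100, end = 200),
                                     data.frame(start = 200, end = 500),
                                     data.frame(start = 500, end = 650)))
  class(plus) <- "transcript_models"
  mir_iv <- function(iv) data.frame(start = L - iv$end, end = L - iv$start)
  minus <- list(g1 = transcript_model("g1", "chr1", "-",
                                      utr5 = mir_iv(plus$g1$utr5),
                                      cds = mir_iv(plus$g1$cds),
                                      utr3 = mir_iv(plus$g1$utr3)))
  class(minus) <- "transcript_models"
  set.seed(77)
  ctr <- sample(150:600, 40, replace = TRUE)
  ps_plus <- peak_set(rep("chr1", 40), ctr - 25, ctr + 26,
                      paste0("p", 1:40), runif(40))
  ps_minus <- peak_set(rep("chr1", 40), L - (ctr + 26), L - (ctr - 25),
                       paste0("p", 1:40), ps_plus$score)
  pr_plus <- metagene_density(ps_plus, plus, bins = 40)
  pr_minus <- metagene_density(ps_minus, minus, bins = 40)
  expect_equal(pr_minus$density, pr_plus$density, tolerance = 1e-12)
})

test_that("the default fixture's profile peaks at the stop codon", {
  fx <- default_fixture()
  grp <- "flower.CS.wt"
  rp <- reproducible_peaks(fx$peaks[[paste0(grp, "_rep1")]],
                           fx$peaks[[paste0(grp, "_rep2")]])
  pr <- metagene_density(rp, fx$models, bins = 100, smoothing_sigma = 2)
  argmax_bin <- which.max(pr$density)
  boundary_bin <- findInterval(0.75, pr$bin_edges)
  expect_lte(abs(argmax_bin - boundary_bin), 2)
  expect_equal(sum(pr$density) * 0.01, 1, tolerance = 1e-9)
})
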