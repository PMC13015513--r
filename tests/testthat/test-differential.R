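test_that("region quantification matches direct summation", {
  ctrl <- make_rle(list(chrA = rep(5, 1000)))
  tgt <- make_rle(list(chrA = rep(10, 1000)))
  regs <- region(c("chrA", "chrA"), c(100, 500), c(200, 900))
  v <- quantify_regions(ctrl, tgt, regs)
  expect_equal(v$value_control, c(5, 5))
  expect_equal(v$value_target, c(10, 10))

  step <- c(rep(1, 300), rep(9, 700))
  v2 <- quantify_regions(make_rle(list(chrA = step)), tgt,
                         region("chrA", 200, 600))
  expect_equal(v2$value_control, mean(step[201:600]))
})

test_that("fold-change threshold is boundary-inclusive in both directions", {
  # ratio exactly 2.0 (pseudocounted) is called; 1.99 is not
  expect_equal(fold_change_call(4, 9, fc_cutoff = 2, pseudocount = 1), "up")
  expect_equal(fold_change_call(9, 4, fc_cutoff = 2, pseudocount = 1), "down")
  expect_equal(fold_change_call(100, 99 * 2.0 - 1 + 0.99, 2, 1), "unchanged")
  expect_equal(fold_change_call(10, 10, fc_cutoff = 1.5), "unchanged")

  set.seed(13)
  ctrl <- runif(300) * 20; tgt <- runif(300) * 20
  calls <- fold_change_call(ctrl, tgt, 2, 1)
  oracle <- vapply(seq_along(ctrl), function(i) {
    r <- (tgt[i] + 1) / (ctrl[i] + 1)
    if (r >= 2) "up" else if (1 / r >= 2) "down" else "unchanged"
  }, character(1))
  expect_equal(calls, oracle)
})

test_that("fold-change antisymmetry: swapping samples swaps up and down", {
  set.seed(14)
  a <- rexp(500) * 10; b <- rexp(500) * 10
  fwd <- fold_change_call(a, b, 2, 1)
  rev <- fold_change_call(b, a, 2, 1)
  expect_equal(fwd == "up", rev == "down")
  expect_equal(fwd == "unchanged", rev == "unchanged")
})

test_that("Poisson p-values match direct pmf summation", {
  # spot value from the two-sided definition
  expect_equal(poisson_test(3, 10), 2 * sum(dpois(10:1000, 3)),
               tolerance = 1e-12)
  # center of the distribution: never significant
  expect_gte(poisson_test(5, 5), 0.5)
  # degenerate zero counts under the pseudo-floor
  expect_equal(poisson_test(0, 0, pseudo_floor = 1),
               min(1, 2 * min(ppois(0, 1), 1)))
  expect_error(poisson_test(3, 3, exposure_ratio = 0), "> 0")
})

test_that("differential calls on identical tracks are all unchanged", {
  sim <- small_sim(seed = 51)
  calls <- call_differential(sim$control, sim$control, sim$candidates)
  expect_false(any(calls$significant))
  expect_true(all(calls$direction == "unchanged"))
})

test_that("planted fold changes are recovered with correct directions", {
  sim <- small_sim(seed = 52)
  out <- tempfile("diffout")
  fit <- suppressMessages(normalize_track(sim$control, sim$target, sim$refs,
                                          outdir = out))
  calls <- suppressMessages(call_differential(
    sim$control, file.path(out, "target.norm.bw"), sim$candidates,
    outdir = out))
  truth <- sim$truth$candidates
  planted <- truth$true_fold != 1
  expect_true(all(calls$significant[planted]))
  expect_true(all(!calls$significant[!planted]))
  sig_planted <- planted & calls$significant
  expect_equal(calls$direction[sig_planted] == "up",
               truth$true_fold[sig_planted] > 1)

  # M/A columns agree with ma_transform on the same values
  ma <- ma_transform(calls$value_control, calls$value_target, 1)
  expect_equal(calls$M, ma$M)
  expect_equal(calls$A, ma$A)

  # outputs: calls table, MA plot, three BED files
  expect_true(all(file.exists(file.path(
    out, c("calls.tsv", "ma.png", "up.bed", "down.bed", "unchanged.bed")))))
  up <- read_regions(file.path(out, "up.bed"))
  expect_equal(length(up), sum(calls$direction == "up"))
  # BED coordinates round-trip exactly
  all_bed <- rbind(calls[, c("chrom", "start", "end")])
  back <- do.call(rbind, lapply(c("up", "down", "unchanged"), function(d) {
    gr <- read_regions(file.path(out, paste0(d, ".bed")))
    if (!length(gr)) return(NULL)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr))
  }))
  expect_equal(nrow(back), nrow(all_bed))
})

test_that("empty region lists produce empty but well-formed outputs", {
  sim <- small_sim(seed = 53)
  out <- tempfile("empty")
  calls <- suppressMessages(call_differential(
    sim$control, sim$target, GenomicRanges::GRanges(), outdir = out))
  expect_equal(nrow(calls), 0L)
  expect_true(file.exists(file.path(out, "calls.tsv")))
  expect_true(file.exists(file.path(out, "up.bed")))
})

test_that("Poisson mode with BH holds the false-positive rate under the null", {
  fps <- vapply(1:3, function(s) {
    sim <- simulate_pair(chrom_sizes = c(t1 = 8e5, t2 = 8e5), n_refs = 30,
                         n_candidates = 150, n_diff = 0, n_outlier_refs = 0,
                         distortion = list(sfbg = 1, sfsig = 1, alpha = 1,
                                           beta = 0),
                         seed = 60 + s, outdir = tempfile("null"))
    calls <- call_differential(sim$control, sim$target, sim$candidates,
                               config = list(stat = "poisson"))
    mean(calls$significant)
  }, numeric(1))
  n <- 3 * 150
  expect_lte(mean(fps), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})
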