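test_that("simulation is byte-identical under a fixed seed", {
  s1 <- small_sim(seed = 71)
  s2 <- small_sim(seed = 71)
  for (f in c("control", "target", "refs", "candidates")) {
    expect_equal(unname(tools::md5sum(s1[[f]])), unname(tools::md5sum(s2[[f]])),
                 info = f)
  }
  s3 <- small_sim(seed = 72)
  expect_false(tools::md5sum(s1$control) == tools::md5sum(s3$control))
})

test_that("identity distortion with zero noise reproduces the control", {
  sim <- small_sim(seed = 73, noise_sd = 0, n_diff = 0, n_outlier_refs = 0,
                   distortion = list(sfbg = 1, sfsig = 1, alpha = 1, beta = 0))
  expect_equal(sim$target_values, sim$control_values, tolerance = 1e-12)
})

test_that("planted differential regions are disjoint from reference sites", {
  sim <- small_sim(seed = 74)
  cand <- GenomicRanges::GRanges(
    sim$truth$candidates$chrom,
    IRanges::IRanges(sim$truth$candidates$start + 1, sim$truth$candidates$end))
  hits <- GenomicRanges::findOverlaps(cand, sim$truth$reference_sites,
                                      maxgap = 2000)
  expect_equal(length(hits), 0L)
})

test_that("canonical truth parameters are exactly recovered without noise", {
  sim <- small_sim(seed = 75, noise_sd = 0)
  fit <- suppressMessages(normalize_track(sim$control, sim$target, sim$refs))
  tr <- sim$truth
  # residual deviation comes only from float32 track storage and any extra
  # filtered sites, not from the estimation formulas
  expect_lt(abs(fit$params$sfbg / tr$true_sfbg - 1), 1e-3)
  expect_lt(abs(fit$params$sfsig / tr$true_sfsig - 1), 0.02)
  expect_lt(abs(fit$params$alpha - tr$true_alpha), 0.02)
  expect_lt(abs(fit$params$beta - tr$true_beta), 0.06)
})

test_that("normalization restores the control aggregate profile", {
  # default-size simulation: at smaller reference counts the beta estimation
  # error (which rescales signal bins by 2^deltabeta) dominates the profile
  sim <- simulate_pair(seed = 76, outdir = tempfile("rt"))
  out <- tempfile("rtout")
  fit <- suppressMessages(normalize_track(sim$control, sim$target, sim$refs,
                                          outdir = out))
  refs <- read_regions(sim$refs)
  pc <- aggregate_profile(extract_signal(sim$control, refs, 40, 1000))
  pn <- aggregate_profile(extract_signal(file.path(out, "target.norm.bw"),
                                         refs, 40, 1000))
  expect_lt(max(abs(pn / pc - 1)), 0.05)
})

test_that("spike-in simulation hits the requested depth ratio", {
  sp <- simulate_spikein(depth_ratio = 2, seed = 77)
  expect_equal(sp$truth$target_total / sp$truth$control_total, 2,
               tolerance = 0.01)
  sp1a <- simulate_spikein(depth_ratio = 1, seed = 78)
  sp1b <- simulate_spikein(depth_ratio = 1, seed = 78)
  expect_equal(unname(tools::md5sum(sp1a$control)),
               unname(tools::md5sum(sp1b$control)))
})

test_that("a genome too small for the requested sites is an error", {
  expect_error(
    simulate_pair(chrom_sizes = c(tiny = 5e4), n_refs = 20, n_candidates = 5,
                  n_diff = 0, n_outlier_refs = 0, seed = 1,
                  outdir = tempfile()),
    "too small")
})
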