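test_that("scaling factors are identified under identity, shift and depth", {
  sig <- 5:8; bg <- c(1:2, 15:16)
  prof <- c(1, 1, 2, 4, 9, 10, 10, 9, 4, 2, rep(0, 6))[1:16]
  prof <- abs(prof) + 1

  sf <- estimate_scaling_factors(prof, prof, sig, bg)
  expect_equal(sf$sfbg, 1)
  expect_equal(sf$sfsig, 1)

  # uniform background shift +b with unchanged peak: sfbg < 1, sfsig = 1
  b <- 2
  tgt <- prof + b
  ctrl_bg <- mean(prof[bg])
  sf <- estimate_scaling_factors(prof, tgt, sig, bg)
  expect_equal(sf$sfbg, ctrl_bg / (ctrl_bg + b))
  expect_equal(sf$sfsig, 1)

  # pure depth factor k
  sf <- estimate_scaling_factors(prof, prof * 3, sig, bg)
  expect_equal(sf$sfbg, 1 / 3)
  expect_equal(sf$sfsig, 1 / 3)

  # flat target profile: no enrichment over background
  expect_error(
    estimate_scaling_factors(prof, rep(2, 16), sig, bg), "no enrichment")
})

test_that("alignment parameters are the z-score moment match", {
  x <- c(1, 2, 3, 5, 8)
  al <- estimate_alignment(x, x)
  expect_equal(al$alpha, 1)
  expect_equal(al$beta, 0)

  # invert a constructed affine map exactly
  a_star <- 1.7; b_star <- -0.9
  y <- (x - b_star) / a_star
  al <- estimate_alignment(x, y)
  expect_equal(al$alpha, a_star, tolerance = 1e-12)
  expect_equal(al$beta, b_star, tolerance = 1e-12)

  # mean/sd plug-in: x (3, 1), y (5, 2) -> alpha 0.5, beta 0.5
  set.seed(4)
  z <- rnorm(100)
  x2 <- 3 + (z - mean(z)) / sd(z)
  y2 <- 5 + 2 * (z - mean(z)) / sd(z)
  al <- estimate_alignment(x2, y2)
  expect_equal(al$alpha, 0.5)
  expect_equal(al$beta, 0.5)

  expect_error(estimate_alignment(x, rep(2, 5)), "constant")

  # applying the map matches control moments exactly
  set.seed(9)
  xr <- rnorm(40, 3, 1.2); yr <- rnorm(40, 6, 0.4)
  al <- estimate_alignment(xr, yr)
  yhat <- al$alpha * yr + al$beta
  expect_equal(mean(yhat), mean(xr), tolerance = 1e-12)
  expect_equal(sd(yhat), sd(xr), tolerance = 1e-12)
})

test_that("noise cutoff sits at the crossing of the log2 densities", {
  set.seed(21)
  bgl <- rnorm(4000, 1.2, 0.5)
  sgl <- rnorm(4000, 3.2, 0.5)
  noise <- estimate_noise_cutoff(bgl, sgl, pseudocount = 1)
  bw <- attr(noise, "bandwidth")
  # equal-variance equal-weight Gaussians cross at the midpoint of means
  expect_lt(abs(attr(noise, "crossing_log2") - 2.2), bw)
  expect_equal(as.numeric(noise), 2^attr(noise, "crossing_log2") - 1)

  # translation equivariance of the crossing
  d <- 1.5
  noise2 <- estimate_noise_cutoff(bgl + d, sgl + d, pseudocount = 1)
  expect_equal(attr(noise2, "crossing_log2"),
               attr(noise, "crossing_log2") + d, tolerance = 0.1)

  # signal mode below background mode: fallback to midpoint, with a message
  expect_message(
    noise3 <- estimate_noise_cutoff(sgl, bgl, pseudocount = 1),
    "midpoint")
  expect_true(attr(noise3, "fallback"))

  expect_error(estimate_noise_cutoff(bgl, bgl, 1), "indistinguishable")
})

test_that("bin classification applies the sfsig-scaled cutoff with ties to background", {
  p <- norm_params(1, 1, 1, 0, noise = 0)
  expect_false(any(classify_bins(rep(0, 5), p)))
  expect_true(all(classify_bins(c(0.1, 5), p)))

  p2 <- norm_params(1, 2, 1, 0, noise = 6)
  expect_equal(as.vector(classify_bins(c(2.9, 3, 3.1), p2)),
               c(FALSE, FALSE, TRUE))  # 3 * 2 == 6 is a tie -> background
})

test_that("two-branch correction matches its closed forms and stays monotone", {
  v <- c(0, 0.5, 2, 4, 30)
  idp <- norm_params(1, 1, 1, 0, noise = 3)
  cls <- classify_bins(v, idp)
  expect_equal(normalize_bins(v, cls, idp, pseudocount = 1), v)

  # background branch: linear in sfbg
  p <- norm_params(0.5, 1, 1, 0, noise = Inf)
  expect_equal(normalize_bins(4, FALSE, p, 1), 2)

  # signal branch with alpha = 1: v * sfsig * 2^beta + c * (2^beta - 1)
  p <- norm_params(1, 1.3, 1, 0.4, noise = 0)
  c0 <- 1
  expect_equal(normalize_bins(v, rep(TRUE, 5), p, c0),
               v * 1.3 * 2^0.4 + c0 * (2^0.4 - 1))

  # strict monotonicity on each branch, and non-negative output
  set.seed(6)
  p <- norm_params(0.8, 1.4, 1.2, -0.7, noise = 5)
  vv <- sort(runif(100) * 100)
  sig <- normalize_bins(vv, rep(TRUE, 100), p, 1)
  bg <- normalize_bins(vv, rep(FALSE, 100), p, 1)
  expect_true(all(diff(sig) > 0))
  expect_true(all(diff(bg) > 0))
  expect_true(all(sig >= 0) && all(bg >= 0))
})

test_that("parameter validation rejects reversed or degenerate slopes", {
  expect_error(norm_params(alpha = 0), "alpha")
  expect_error(norm_params(alpha = -1), "reverses")
  expect_error(norm_params(sfbg = 0), "sfbg")
})

test_that("spike-in ratio factor is the control/target count ratio", {
  expect_equal(spikein_ratio_factor(5, 5), 1)
  expect_equal(spikein_ratio_factor(2e6, 4e6), 0.5)
  expect_error(spikein_ratio_factor(0, 1), "> 0")
})
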