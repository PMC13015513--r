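test_that("M-A transform has the closed-form values and inverts exactly", {
  ma <- ma_transform(c(1, 2, 3), c(1, 2, 3), pseudocount = 0.5)
  expect_equal(ma$M, rep(0, 3))

  ma <- ma_transform(3, 15, pseudocount = 1)
  expect_equal(ma$M, 2)
  expect_equal(ma$A, 3)

  set.seed(1)
  x <- rexp(50) * 10; y <- rexp(50) * 10
  ma <- ma_transform(x, y, pseudocount = 1)
  expect_equal(2^(ma$A - ma$M / 2) - 1, x)
  expect_equal(2^(ma$A + ma$M / 2) - 1, y)

  expect_error(ma_transform(1:3, 1:2), "length")
})

test_that("Mahalanobis distances match a brute-force per-point computation", {
  set.seed(11)
  pts <- data.frame(M = rnorm(200, sd = 0.5), A = rnorm(200, mean = 4))
  res <- mahalanobis_filter(pts, 0.99)
  mu <- colMeans(as.matrix(pts))
  sig_inv <- solve(stats::cov(as.matrix(pts)))
  brute <- apply(as.matrix(pts), 1, function(p) {
    d <- p - mu
    drop(t(d) %*% sig_inv %*% d)
  })
  expect_equal(res$d2, brute, tolerance = 1e-10)
  expect_equal(sort(c(res$kept, res$removed)), 1:200)
})

test_that("a single gross outlier among near-identical points is removed", {
  pts <- data.frame(M = c(rep(0, 20), 5), A = c(rep(3, 20), 8))
  expect_message(res <- mahalanobis_filter(pts, 0.99), "singular")
  expect_equal(res$removed, 21L)
})

test_that("Mahalanobis filtering is invariant to joint affine rescaling", {
  set.seed(5)
  pts <- cbind(M = rnorm(300), A = rnorm(300, 2))
  r1 <- mahalanobis_filter(pts, 0.975)
  r2 <- mahalanobis_filter(sweep(pts * 7, 2, c(-3, 11), "+"), 0.975)
  expect_equal(r1$removed, r2$removed)
  expect_equal(r1$d2, r2$d2, tolerance = 1e-9)
})

test_that("null removal fraction matches the chi-squared quantile", {
  set.seed(19)
  pts <- cbind(M = rnorm(10000), A = rnorm(10000))
  res <- mahalanobis_filter(pts, 0.99)
  frac <- length(res$removed) / 10000
  expect_true(abs(frac - 0.01) < 0.005)
  expect_error(mahalanobis_filter(pts[1:2, ], 0.99), "at least 3")
})

test_that("QC metrics behave under identity and pure scaling", {
  set.seed(2)
  m <- matrix(rexp(200) + 1, nrow = 10)
  qc <- compute_qc(m, m, signal_window = 9:12, background_window = c(1:3, 18:20))
  expect_equal(qc$background_scaling, 1)
  expect_equal(qc$snr_control, qc$snr_target)

  qc2 <- compute_qc(m, 2 * m, signal_window = 9:12,
                    background_window = c(1:3, 18:20))
  expect_equal(qc2$background_scaling, 0.5)
  expect_equal(qc2$snr_control, qc2$snr_target)
})

test_that("SNR reflects the planted peak-to-background ratio", {
  set.seed(8)
  h <- 12; b <- 3
  template <- b + h * exp(-((1:40 - 20.5)^2) / 18)
  m <- matrix(rep(template, each = 200) * rlnorm(8000, 0, 0.05), nrow = 200)
  qc <- compute_qc(m, m, signal_window = 19:22, background_window = c(1:5, 36:40))
  expect_equal(qc$snr_control, (h + b) / b, tolerance = 0.06)
})

test_that("QC report serializes as a two-column TSV", {
  m <- matrix(rexp(80) + 1, nrow = 4)
  qc <- compute_qc(m, m, 9:12, c(1:3, 18:20))
  f <- tempfile(fileext = ".tsv")
  write_qc(qc, f)
  df <- read.delim(f)
  expect_named(df, c("metric", "value"))
  expect_true("background_scaling" %in% df$metric)
})
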