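#' M-A transform of paired per-site signals
#'
#' M is the log2 ratio target/control and A the average log2 signal, both
#' computed after adding a pseudocount so zero-coverage sites stay finite:
#' `M = log2(y + c) - log2(x + c)`, `A = (log2(y + c) + log2(x + c)) / 2`.
#'
#' @param x Per-site control means (>= 0).
#' @param y Per-site target means (>= 0), same length as `x`.
#' @param pseudocount Positive value `c` added before log2.
#' @return A data.frame with columns `region_index`, `M`, `A`.
#' @export
ma_transform <- function(x, y, pseudocount = 1) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  stopifnot(pseudocount > 0, all(x >= 0), all(y >= 0))
  lx <- log2(x + pseudocount)
  ly <- log2(y + pseudocount)
  data.frame(region_index = seq_along(x), M = ly - lx, A = (ly + lx) / 2)
}

#' Remove outlier reference sites by Mahalanobis distance in M-A space
#'
#' Squared Mahalanobis distances are computed from the sample mean and sample
#' covariance of all (M, A) points in a single pass; points beyond the
#' chi-squared (2 df) quantile are flagged as outliers. With `two_pass =
#' TRUE` the statistics are re-estimated once on the surviving points and the
#' filter re-applied. A singular covariance (e.g. all M identical) falls back
#' to independent per-axis z-score filtering at the matching normal quantile,
#' with a message.
#'
#' @param ma A data.frame from [ma_transform()] (columns `M`, `A`), or a
#'   two-column matrix.
#' @param chi2_quantile Probability defining the cutoff `qchisq(q, df = 2)`.
#' @param two_pass Re-estimate mean/covariance after the first removal.
#' @return A list with `kept`, `removed` (integer indices) and `d2`
#'   (squared distances from the final statistics).
#' @export
mahalanobis_filter <- function(ma, chi2_quantile = 0.99, two_pass = FALSE) {
  pts <- as.matrix(if (is.data.frame(ma)) ma[, c("M", "A")] else ma)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 reference sites for outlier filtering")
  stopifnot(chi2_quantile > 0, chi2_quantile < 1)
  pass <- function(p) {
    mu <- colMeans(p)
    sig <- stats::cov(p)
    ok <- is.finite(determinant(sig)$modulus) &&
      abs(det(sig)) > 1e-12 * prod(pmax(diag(sig), .Machine$double.eps))
    if (!ok) {
      message("singular M-A covariance; falling back to per-axis z-scores")
      z <- sweep(p, 2, mu)
      sds <- apply(p, 2, stats::sd)
      sds[sds == 0] <- Inf  # a constant axis can never flag an outlier
      z <- sweep(z, 2, sds, "/")
      zcut <- stats::qnorm(1 - (1 - chi2_quantile) / 2)
      d2 <- apply(z^2, 1, max)
      return(list(d2 = d2, cut = zcut^2))
    }
    list(d2 = stats::mahalanobis(p, mu, sig), cut = stats::qchisq(chi2_quantile, df = 2))
  }
  res <- pass(pts)
  if (two_pass) {
    keep1 <- res$d2 <= res$cut
    if (sum(keep1) >= 3L) {
      stats2 <- pass(pts[keep1, , drop = FALSE])
      mu <- colMeans(pts[keep1, , drop = FALSE])
      sig <- stats::cov(pts[keep1, , drop = FALSE])
      res <- list(d2 = stats::mahalanobis(pts, mu, sig), cut = stats2$cut)
    }
  }
  removed <- which(res$d2 > res$cut)
  list(kept = setdiff(seq_len(n), removed), removed = removed, d2 = res$d2)
}

#' Quality metrics from paired reference-site signal matrices
#'
#' Signal-to-noise is the ratio of the aggregate profile's mean over the
#' central signal bins to its mean over the flank background bins, per
#' sample; `background_scaling` is the control's background mean over the
#' target's (the multiplicative factor that would equalize backgrounds).
#'
#' @param control_matrix,target_matrix Matrices from [extract_signal()]
#'   sharing region set and bin count; `NA` marks masked bins.
#' @param signal_window Integer vector of central bin indices.
#' @param background_window Integer vector of flank bin indices, disjoint
#'   from `signal_window`.
#' @return An object of class `qc_report`: a list with counts, SNRs,
#'   `background_scaling`, and per-sample log2 summary statistics.
#' @export
compute_qc <- function(control_matrix, target_matrix,
                       signal_window, background_window) {
  stopifnot(identical(dim(control_matrix), dim(target_matrix)),
            length(signal_window) > 0, length(background_window) > 0,
            length(intersect(signal_window, background_window)) == 0)
  pc <- aggregate_profile(control_matrix)
  pt <- aggregate_profile(target_matrix)
  bg_c <- mean(pc[background_window])
  bg_t <- mean(pt[background_window])
  if (bg_c <= 0 || bg_t <= 0) {
    stop("zero background mean; widen the background flanks or increase ",
         "the pseudocount")
  }
  sig_means_c <- rowMeans(control_matrix[, signal_window, drop = FALSE], na.rm = TRUE)
  sig_means_t <- rowMeans(target_matrix[, signal_window, drop = FALSE], na.rm = TRUE)
  summ <- function(v) c(mean = mean(v, na.rm = TRUE),
                        sd = stats::sd(v[!is.na(v)]))
  structure(list(
    n_references_input = nrow(control_matrix),
    n_outliers_removed = 0L,
    background_scaling = bg_c / bg_t,
    snr_control = mean(pc[signal_window]) / bg_c,
    snr_target = mean(pt[signal_window]) / bg_t,
    log2_signal_control = summ(log2(sig_means_c + 1)),
    log2_signal_target = summ(log2(sig_means_t + 1)),
    log2_background_control = summ(log2(control_matrix[, background_window] + 1)),
    log2_background_target = summ(log2(target_matrix[, background_window] + 1))
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Reference-site QC\n")
  cat(sprintf("  references: %d (outliers removed: %d)\n",
              x$n_references_input, x$n_outliers_removed))
  cat(sprintf("  background scaling (control/target): %.4f\n",
              x$background_scaling))
  cat(sprintf("  SNR control: %.2f   SNR target: %.2f\n",
              x$snr_control, x$snr_target))
  invisible(x)
}

#' Serialize a QC report as TSV
#'
#' @param qc A `qc_report` from [compute_qc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc <- function(qc, path) {
  flat <- unlist(qc)
  utils::write.table(
    data.frame(metric = names(flat), value = as.numeric(flat)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' MA scatter plot with outliers highlighted
#'
#' @param ma Data.frame from [ma_transform()].
#' @param removed Integer indices of removed points.
#' @param path PNG output path.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
plot_ma <- function(ma, removed = integer(0), path, main = "MA plot") {
  grDevices::png(path, width = 900, height = 700, res = 120)
  on.exit(grDevices::dev.off())
  col <- rep("#00000066", nrow(ma))
  col[removed] <- "#d62728"
  plot(ma$A, ma$M, pch = 16, cex = 0.6, col = col,
       xlab = "A (mean log2 signal)", ylab = "M (log2 ratio target/control)",
       main = main)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  if (length(removed)) {
    graphics::legend("topright", legend = c("kept", "removed"),
                     col = c("#000000", "#d62728"), pch = 16, bty = "n")
  }
  invisible(path)
}
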