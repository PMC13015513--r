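#' Normalization parameter set
#'
#' Bundles the five quantities driving the two-tier correction: the
#' background scaling factor `sfbg`, the reference-signal scaling factor
#' `sfsig`, the log2-space slope `alpha` and intercept `beta`, and the
#' background/signal `noise` cutoff in track units, together with each
#' field's provenance (`estimated`, `override`, `spikein_ratio`,
#' `spikein_profile`, `fixed`).
#'
#' @param sfbg,sfsig Multiplicative scaling factors, > 0.
#' @param alpha Log2-space slope, > 0 (a non-positive slope would reverse
#'   signal ranking and is rejected).
#' @param beta Log2-space intercept.
#' @param noise Signal/background cutoff in track units, >= 0 (`Inf` means
#'   every bin is background).
#' @param source Named character vector of provenance flags, one per field.
#' @return An object of class `norm_params`.
#' @export
norm_params <- function(sfbg = 1, sfsig = 1, alpha = 1, beta = 0, noise = 0,
                        source = c(sfbg = "fixed", sfsig = "fixed",
                                   alpha = "fixed", beta = "fixed",
                                   noise = "fixed")) {
  stopifnot(sfbg > 0, sfsig > 0, is.finite(beta), noise >= 0)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("alpha must be > 0: a non-positive log2 slope reverses signal ranking")
  }
  structure(list(sfbg = sfbg, sfsig = sfsig, alpha = alpha, beta = beta,
                 noise = noise, source = source),
            class = "norm_params")
}

#' @export
print.norm_params <- function(x, ...) {
  cat("Two-tier normalization parameters\n")
  for (f in c("sfbg", "sfsig", "alpha", "beta", "noise")) {
    cat(sprintf("  %-6s %10.5g  [%s]\n", f, x[[f]], x$source[[f]]))
  }
  invisible(x)
}

#' Write a parameter report as TSV
#' @param params A `norm_params`.
#' @param path Output path.
#' @param n_outliers Outlier reference-site count to record alongside.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path, n_outliers = NA_integer_) {
  f <- c("sfbg", "sfsig", "alpha", "beta", "noise")
  df <- data.frame(parameter = c(f, "n_outliers_removed"),
                   value = c(unlist(params[f]), n_outliers),
                   source = c(params$source[f], "estimated"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate background and signal scaling factors from aggregate profiles
#'
#' `sfbg` is the ratio of control to target background (flank-window means of
#' the aggregate profiles). `sfsig` is the ratio of the background-subtracted
#' central signal means, so that a pure background shift does not leak into
#' the signal scale factor; set `subtract_background = FALSE` to use raw
#' central means instead.
#'
#' @param control_profile,target_profile Per-bin aggregate profiles of equal
#'   length (from [aggregate_profile()]).
#' @param signal_window Central bin indices.
#' @param background_window Flank bin indices, disjoint from `signal_window`.
#' @param subtract_background Subtract each sample's own background mean from
#'   its central mean before taking the signal ratio.
#' @return A list with `sfbg` and `sfsig`.
#' @export
estimate_scaling_factors <- function(control_profile, target_profile,
                                     signal_window, background_window,
                                     subtract_background = TRUE) {
  stopifnot(length(control_profile) == length(target_profile),
            length(signal_window) > 0, length(background_window) > 0,
            length(intersect(signal_window, background_window)) == 0)
  bg_c <- mean(control_profile[background_window])
  bg_t <- mean(target_profile[background_window])
  if (bg_c <= 0 || bg_t <= 0) stop("non-positive background mean")
  sfbg <- bg_c / bg_t
  sig_c <- mean(control_profile[signal_window])
  sig_t <- mean(target_profile[signal_window])
  if (subtract_background) {
    sig_c <- sig_c - bg_c
    sig_t <- sig_t - bg_t
  }
  if (sig_c <= 0 || sig_t <= 0) {
    stop("reference sites show no enrichment over background; ",
         "cannot estimate sfsig")
  }
  list(sfbg = sfbg, sfsig = sig_c / sig_t)
}

#' Log2 affine alignment parameters (z-score map)
#'
#' Matches the target reference-signal distribution to the control's in log2
#' space by moment matching: `alpha = sd(x) / sd(y)` and
#' `beta = mean(x) - alpha * mean(y)`, so that `alpha * y + beta` has exactly
#' the control's mean and standard deviation.
#'
#' @param x_log2 Log2 control per-site signals.
#' @param y_log2 Log2 target per-site signals (already sfsig-scaled before
#'   the log2).
#' @return A list with `alpha` and `beta`.
#' @export
estimate_alignment <- function(x_log2, y_log2) {
  if (length(x_log2) != length(y_log2)) stop("length mismatch")
  if (length(x_log2) < 3L) stop("need at least 3 reference sites")
  sy <- stats::sd(y_log2)
  if (sy == 0) stop("target reference signals are constant; cannot align")
  alpha <- stats::sd(x_log2) / sy
  list(alpha = alpha, beta = mean(x_log2) - alpha * mean(y_log2))
}

#' Noise cutoff from the intersection of log2 distributions
#'
#' Fits a Gaussian kernel density (Silverman bandwidth) to the background and
#' signal log2 samples on a common grid and takes the crossing point of the
#' two densities between the background mode and the signal mode. If the
#' signal mode does not lie above the background mode, or no crossing exists
#' between the modes, the midpoint of the two sample means is used instead
#' (with a message). The cutoff is returned in linear track units:
#' `2^crossing - pseudocount`, floored at 0.
#'
#' @param background_log2 Log2 values of background-like bins (pseudocount
#'   already added before the log2).
#' @param signal_log2 Log2 values of reference signal-window bins.
#' @param pseudocount The pseudocount used in the log2 transform.
#' @return The noise cutoff (track units) with attributes `crossing_log2`,
#'   `bandwidth` and `fallback`.
#' @export
estimate_noise_cutoff <- function(background_log2, signal_log2,
                                  pseudocount = 1) {
  stopifnot(length(background_log2) > 0, length(signal_log2) > 0)
  mb <- mean(background_log2); ms <- mean(signal_log2)
  if (abs(mb - ms) < 1e-9 &&
      abs(stats::sd(background_log2) - stats::sd(signal_log2)) < 1e-9) {
    stop("background and signal log2 distributions are indistinguishable; ",
         "supply a manual noise override")
  }
  lo <- min(background_log2, signal_log2)
  hi <- max(background_log2, signal_log2)
  db <- stats::density(background_log2, bw = "nrd0", from = lo, to = hi, n = 1024)
  ds <- stats::density(signal_log2, bw = stats::bw.nrd0(signal_log2),
                       from = lo, to = hi, n = 1024)
  grid <- db$x
  mode_b <- grid[which.max(db$y)]
  mode_s <- grid[which.max(ds$y)]
  crossing <- NA_real_
  fallback <- FALSE
  if (mode_s > mode_b) {
    between <- which(grid > mode_b & grid < mode_s)
    diff_d <- db$y[between] - ds$y[between]
    flip <- which(diff_d[-length(diff_d)] > 0 & diff_d[-1] <= 0)
    if (length(flip)) {
      i <- between[flip[1L]]
      # linear interpolation between the two grid points bracketing the sign change
      d1 <- db$y[i] - ds$y[i]; d2 <- db$y[i + 1] - ds$y[i + 1]
      w <- if (d1 == d2) 0.5 else d1 / (d1 - d2)
      crossing <- grid[i] + w * (grid[i + 1] - grid[i])
    }
  }
  if (is.na(crossing)) {
    fallback <- TRUE
    crossing <- (mb + ms) / 2
    message("no density crossing between modes; ",
            "using midpoint of log2 means as noise cutoff")
  }
  structure(max(2^crossing - pseudocount, 0),
            crossing_log2 = crossing, bandwidth = db$bw, fallback = fallback)
}

#' Classify genome bins as background or signal
#'
#' A bin is signal when its sfsig-scaled value exceeds the noise cutoff
#' (`value * sfsig > noise`); ties go to background.
#'
#' @param values Per-bin track values of the target sample.
#' @param params A `norm_params` with `noise` set.
#' @return Logical vector `is_signal` with attribute `noise`.
#' @export
classify_bins <- function(values, params) {
  stopifnot(inherits(params, "norm_params"), !is.na(params$noise))
  structure(values * params$sfsig > params$noise, noise = params$noise)
}

#' Apply the two-tier per-bin correction
#'
#' Background bins are scaled linearly by `sfbg`; signal bins are scaled by
#' `sfsig`, mapped affinely in log2 space with slope `alpha` and intercept
#' `beta`, and exponentiated back:
#' `2^(alpha * log2(v * sfsig + c) + beta) - c`, floored at 0.
#'
#' @param values Per-bin track values.
#' @param is_signal Logical classification from [classify_bins()].
#' @param params A `norm_params`.
#' @param pseudocount The shared pseudocount `c`.
#' @return Normalized per-bin values, finite and >= 0.
#' @export
normalize_bins <- function(values, is_signal, params, pseudocount = 1) {
  if (length(is_signal) != length(values)) {
    stop("classification length must match values")
  }
  out <- values * params$sfbg
  if (any(is_signal)) {
    v <- values[is_signal]
    out[is_signal] <- pmax(
      2^(params$alpha * log2(v * params$sfsig + pseudocount) + params$beta) -
        pseudocount, 0)
  }
  out
}

#' Global scaling factor from spike-in totals
#'
#' The ratio of control to target spike-in signal (or read counts). Applied
#' in single-factor mode the factor multiplies every bin
#' (`sfbg = sfsig = factor`, `alpha = 1`, `beta = 0`).
#'
#' @param control_spikein_count,target_spikein_count Positive totals.
#' @return The scalar factor control/target.
#' @export
spikein_ratio_factor <- function(control_spikein_count, target_spikein_count) {
  if (control_spikein_count <= 0 || target_spikein_count <= 0) {
    stop("spike-in counts must be > 0")
  }
  control_spikein_count / target_spikein_count
}

# ---- window helpers ---------------------------------------------------------

# Bin indices of the wide profile matrix falling in the central signal window
# and in the background flanks [flank_inner, flank_outer) on both sides.
profile_windows <- function(config) {
  w <- config$profile_bin
  n <- (2 * config$flank_outer) %/% w
  off_start <- -config$flank_outer + (seq_len(n) - 1L) * w  # bp from center
  off_end <- off_start + w
  sig_half <- config$signal_frac * config$flank
  list(
    n_bins = n,
    signal = which(off_start >= -sig_half & off_end <= sig_half),
    background = which((off_start >= config$flank_inner & off_end <= config$flank_outer) |
                         (off_end <= -config$flank_inner & off_start >= -config$flank_outer))
  )
}

# NA-mask background-window bins of `mat` whose genomic span overlaps another
# reference site (sites taken as center +/- mask_halfwidth).
mask_reference_flanks <- function(mat, regions, background_window, config,
                                  mask_halfwidth = 500) {
  w <- config$profile_bin
  centers <- floor((GenomicRanges::start(regions) - 1 +
                      GenomicRanges::end(regions)) / 2)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  bw_start0 <- rep(centers, each = length(background_window)) -
    config$flank_outer + (rep.int(background_window, length(regions)) - 1L) * w
  bins <- GenomicRanges::GRanges(
    rep(chrom, each = length(background_window)),
    IRanges::IRanges(start = pmax(bw_start0 + 1L, 1L), width = w))
  sites <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = pmax(centers + 1L - mask_halfwidth, 1L),
                            end = centers + mask_halfwidth))
  hits <- GenomicRanges::findOverlaps(bins, sites)
  # a background bin of region i is masked if it overlaps any OTHER site
  bin_region <- rep(seq_along(regions), each = length(background_window))
  drop <- unique(S4Vectors::queryHits(hits)[
    bin_region[S4Vectors::queryHits(hits)] != S4Vectors::subjectHits(hits)])
  if (length(drop)) {
    rows <- bin_region[drop]
    cols <- background_window[(drop - 1L) %% length(background_window) + 1L]
    mat[cbind(rows, cols)] <- NA_real_
  }
  mat
}

# ---- estimation + application orchestrators --------------------------------

# Shared estimation engine: wide profile extraction, M-A outlier filtering,
# QC, scaling factors, alignment, noise cutoff. Returns everything the
# applying stage and the reports need.
estimate_params <- function(control, target, refs, config) {
  ctrl <- read_track(control)
  tgt <- read_track(target)
  refs <- if (is.character(refs)) read_regions(refs) else refs
  if (length(refs) < 3L) stop("need at least 3 reference regions")
  win <- profile_windows(config)
  cm <- extract_signal(ctrl, refs, n_bins = win$n_bins,
                       flank = config$flank_outer)
  tm <- extract_signal(tgt, refs, n_bins = win$n_bins,
                       flank = config$flank_outer)
  x_raw <- rowMeans(cm[, win$signal, drop = FALSE])
  y_raw <- rowMeans(tm[, win$signal, drop = FALSE])
  ma <- ma_transform(x_raw, y_raw, config$pseudocount)
  filt <- mahalanobis_filter(ma, config$chi2_quantile,
                             two_pass = config$two_pass)
  if (length(filt$kept) < 3L) {
    stop("fewer than 3 reference sites survive outlier filtering")
  }
  cm <- mask_reference_flanks(cm, refs, win$background, config)
  tm <- mask_reference_flanks(tm, refs, win$background, config)
  cmk <- cm[filt$kept, , drop = FALSE]
  tmk <- tm[filt$kept, , drop = FALSE]
  qc <- compute_qc(cmk, tmk, win$signal, win$background)
  qc$n_references_input <- length(refs)
  qc$n_outliers_removed <- length(filt$removed)

  pc <- aggregate_profile(cmk)
  pt <- aggregate_profile(tmk)
  sf <- estimate_scaling_factors(pc, pt, win$signal, win$background,
                                 subtract_background = config$subtract_background)
  c0 <- config$pseudocount
  al <- estimate_alignment(log2(x_raw[filt$kept] + c0),
                           log2(sf$sfsig * y_raw[filt$kept] + c0))
  bg_vals <- c(as.vector(cmk[, win$background]),
               sf$sfsig * as.vector(tmk[, win$background]))
  bg_vals <- bg_vals[!is.na(bg_vals)]
  sig_vals <- c(as.vector(cmk[, win$signal]),
                sf$sfsig * as.vector(tmk[, win$signal]))
  noise <- estimate_noise_cutoff(log2(bg_vals + c0), log2(sig_vals + c0), c0)
  list(sf = sf, alignment = al, noise = noise, qc = qc, ma = ma,
       filter = filt, refs = refs,
       profiles = list(control = pc, target = pt, windows = win))
}

# Merge estimates with user overrides into a norm_params, recording sources.
resolve_params <- function(est, config, default_source = "estimated") {
  take <- function(field, est_value) {
    ov <- config[[field]]
    if (!is.null(ov) && !is.na(ov)) list(v = ov, s = "override")
    else list(v = est_value, s = default_source)
  }
  p <- list(sfbg = take("sfbg", est$sf$sfbg),
            sfsig = take("sfsig", est$sf$sfsig),
            alpha = take("alpha", est$alignment$alpha),
            beta = take("beta", est$alignment$beta),
            noise = take("noise", as.numeric(est$noise)))
  norm_params(p$sfbg$v, p$sfsig$v, p$alpha$v, p$beta$v, p$noise$v,
              source = vapply(p, `[[`, character(1), "s"))
}

#' Normalize a target coverage track against a control
#'
#' The full two-tier pipeline: per-site signal extraction at the reference
#' regions, M-A transformation and Mahalanobis outlier removal, QC metrics,
#' estimation of the five parameters (`sfbg`, `sfsig`, `alpha`, `beta`,
#' `noise`) from the surviving sites, genome binning, background/signal
#' classification, and per-bin correction. The control track is the anchor
#' and is never modified. Any parameter supplied in `config` overrides its
#' estimate and is flagged `source = "override"`.
#'
#' Modes: `"two-tier"` (default) applies the full model; `"background-only"`
#' multiplies every bin by `sfbg` (for assays with modest signal-to-background
#' contrast, e.g. nucleosome occupancy); `"single-factor"` multiplies every
#' bin by one global factor (supply it as `sfbg`, e.g. a spike-in read-count
#' ratio from [spikein_ratio_factor()]).
#'
#' @param control,target BigWig paths or `RleList`s.
#' @param refs Reference regions: BED path or `GRanges`.
#' @param config A configuration list from [default_config()]; individual
#'   fields may be overridden there.
#' @param outdir Optional output directory; when given, the normalized track
#'   (`<target>.norm.bw`), `params.tsv`, `qc.tsv`, `ma.png` and
#'   `noise_cutoff.png` are written there.
#' @param chrom_sizes Optional named lengths; defaults to the target track's
#'   own chromosome table.
#' @return An object of class `tiernorm_fit`: list with `params`
#'   (`norm_params`), `qc` (`qc_report`), `ma`, `filter`, `profiles`, `bins`
#'   (`GRanges` of genome tiles), `values` (normalized per-bin values),
#'   `classification`, and `files` (paths written, if any).
#' @export
normalize_track <- function(control, target, refs,
                            config = default_config(), outdir = NULL,
                            chrom_sizes = NULL) {
  config <- utils::modifyList(default_config(), config)
  tgt <- read_track(target)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.numeric(lengths(tgt)), names(tgt))
  }
  mode <- match.arg(config$mode, c("two-tier", "background-only",
                                   "single-factor"))
  est <- NULL
  if (mode == "single-factor") {
    if (is.null(config$sfbg)) {
      stop("single-factor mode requires the factor as config$sfbg")
    }
    fac <- config$sfbg
    params <- norm_params(fac, fac, 1, 0, Inf,
                          source = c(sfbg = "override", sfsig = "override",
                                     alpha = "fixed", beta = "fixed",
                                     noise = "fixed"))
  } else if (all(!vapply(config[c("sfbg", "sfsig", "alpha", "beta", "noise")],
                         is.null, logical(1)))) {
    message("all five parameters supplied; estimation stages skipped")
    params <- norm_params(config$sfbg, config$sfsig, config$alpha,
                          config$beta, config$noise,
                          source = c(sfbg = "override", sfsig = "override",
                                     alpha = "override", beta = "override",
                                     noise = "override"))
  } else {
    est <- estimate_params(control, target, refs, config)
    params <- resolve_params(est, config)
    if (mode == "background-only") {
      # only the background scaling factor is applied; everything is background
      params <- norm_params(params$sfbg, 1, 1, 0, Inf,
                            source = c(params$source["sfbg"],
                                       sfsig = "fixed", alpha = "fixed",
                                       beta = "fixed", noise = "fixed"))
    }
  }
  bins <- bin_genome(chrom_sizes, config$bin_size)
  values <- bin_track(tgt, bins)
  is_signal <- if (mode == "two-tier") classify_bins(values, params)
               else rep(FALSE, length(values))
  norm <- normalize_bins(values, is_signal, params, config$pseudocount)

  files <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    base <- if (is.character(target)) {
      sub("\\.(bw|bigwig)$", "", basename(target), ignore.case = TRUE)
    } else "target"
    files$track <- file.path(outdir, paste0(base, ".norm.bw"))
    write_track(bins, norm, chrom_sizes, files$track)
    files$params <- write_params(params, file.path(outdir, "params.tsv"),
                                 n_outliers = if (!is.null(est))
                                   length(est$filter$removed) else NA_integer_)
    if (!is.null(est)) {
      files$qc <- write_qc(est$qc, file.path(outdir, "qc.tsv"))
      files$ma <- plot_ma(est$ma, est$filter$removed,
                          file.path(outdir, "ma.png"),
                          main = "Reference sites (M-A)")
      files$noise <- plot_noise_cutoff(est, config,
                                       file.path(outdir, "noise_cutoff.png"))
    }
  }
  structure(list(params = params, qc = est$qc, ma = est$ma,
                 filter = est$filter, profiles = est$profiles,
                 bins = bins, values = norm, input_values = values,
                 classification = is_signal, mode = mode, config = config,
                 files = files),
            class = "tiernorm_fit")
}

#' @export
print.tiernorm_fit <- function(x, ...) {
  cat("Two-tier track normalization (mode: ", x$mode, ")\n", sep = "")
  print(x$params)
  if (!is.null(x$qc)) print(x$qc)
  if (length(x$classification)) {
    cat(sprintf("  bins: %d signal / %d background\n",
                sum(x$classification), sum(!x$classification)))
  }
  invisible(x)
}

#' Derive normalization parameters from spike-in tracks
#'
#' Runs the estimation stages (outlier filtering, scaling factors, alignment,
#' noise cutoff) on spike-in coverage tracks over spike-in reference regions,
#' without applying them. The returned parameters are flagged
#' `source = "spikein_profile"` and can be passed as overrides when
#' normalizing the endogenous target track.
#'
#' @param control_spikein,target_spikein Spike-in BigWig paths or `RleList`s.
#' @param spikein_regions Spike-in reference regions (BED path or `GRanges`).
#' @param config Configuration list (see [default_config()]).
#' @return A `norm_params` with spike-in provenance.
#' @export
spikein_profile_params <- function(control_spikein, target_spikein,
                                   spikein_regions,
                                   config = default_config()) {
  config <- utils::modifyList(default_config(), config)
  est <- estimate_params(control_spikein, target_spikein, spikein_regions,
                         config)
  resolve_params(est, config, default_source = "spikein_profile")
}

# Diagnostic plot of the background/signal log2 densities and the cutoff.
plot_noise_cutoff <- function(est, config, path) {
  grDevices::png(path, width = 900, height = 700, res = 120)
  on.exit(grDevices::dev.off())
  win <- est$profiles$windows
  c0 <- config$pseudocount
  bg <- log2(c(est$profiles$control[win$background],
               est$profiles$target[win$background] * est$sf$sfsig) + c0)
  sig <- log2(c(est$profiles$control[win$signal],
                est$profiles$target[win$signal] * est$sf$sfsig) + c0)
  db <- stats::density(bg); ds <- stats::density(sig)
  plot(db, col = "steelblue", lwd = 2, main = "Noise cutoff",
       xlab = "log2(signal + pseudocount)",
       xlim = range(db$x, ds$x), ylim = range(0, db$y, ds$y))
  graphics::lines(ds, col = "firebrick", lwd = 2)
  graphics::abline(v = attr(est$noise, "crossing_log2"), lty = 2)
  graphics::legend("topright", c("background", "signal"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(path)
}
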