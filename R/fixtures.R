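#' Simulate a paired control/target track set with known ground truth
#'
#' Builds a control coverage track as a flat background plus Gaussian-shaped
#' peaks at reference sites and candidate regions (heights drawn lognormally
#' per site), then derives the target track by pushing the control's latent
#' signal through the *inverse* of the two-tier normalization map, so that
#' normalizing the target with the true parameters restores the control:
#' bins below the background/signal boundary are divided by `sfbg`, bins
#' above it pass through the inverse of the sfsig/log2-affine signal map.
#' Planted differential candidates get their fold change applied to the
#' target peak before the distortion; planted outlier reference sites get an
#' independent fold change so that Mahalanobis filtering has true positives.
#' Both tracks finally receive independent multiplicative lognormal noise
#' per bin (unit mean).
#'
#' Sites are laid out left to right on a jittered slot grid (wide slots for
#' reference sites so their 2-4 kb background flanks stay clear of other
#' peaks, narrow slots for candidates), which guarantees disjoint placement;
#' a genome too small for the requested counts is an error. Site centers are
#' snapped to bin boundaries so extraction windows align with track bins.
#'
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param n_refs Number of reference sites.
#' @param n_candidates Number of candidate regions for differential analysis.
#' @param n_diff Number of candidates with a planted fold change (alternating
#'   up `diff_fold` and down `1/diff_fold`).
#' @param n_outlier_refs Reference sites violated with an independent fold
#'   change (alternating 5x and 0.2x).
#' @param distortion List with `sfbg`, `sfsig`, `alpha`, `beta`: the applied
#'   signal map. Because rescaling `sfsig` can be absorbed into
#'   `alpha`/`beta`, the returned truth re-expresses the signal-map triple in
#'   the canonical parameterization the estimation convention identifies
#'   (see Details in the returned `truth`); `sfbg` is identified as given.
#' @param diff_fold Planted fold change for differential candidates.
#' @param noise_sd Sdlog of the per-bin multiplicative lognormal noise.
#' @param background Flat background level (track units).
#' @param peak_height_meanlog,peak_height_sdlog Lognormal peak-height law.
#' @param peak_sd Gaussian peak standard deviation (bp).
#' @param signal_halfwidth Half-width (bp) of the central signal window the
#'   site-level distortion is calibrated on; match the analysis windows
#'   (`signal_frac * flank` of the configuration, 200 bp at defaults).
#' @param bin_size Track bin width (bp).
#' @param pseudocount Pseudocount of the normalization model being inverted.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param outdir Directory for `control.bw`, `target.bw`, `refs.bed`,
#'   `candidates.bed`, `chrom.sizes`.
#' @return A list with the file paths, plus `truth`: `true_sfbg`,
#'   `true_sfsig`, `true_alpha`, `true_beta`, `site_mean_control` (noiseless
#'   central-window means), `candidates` (data.frame with `true_fold`),
#'   `reference_sites` (`GRanges`), `planted_outlier_sites` (indices), and
#'   `seed`.
#' @export
simulate_pair <- function(chrom_sizes = c(simA = 3e6, simB = 3e6),
                          n_refs = 400, n_candidates = 100, n_diff = 20,
                          n_outlier_refs = 8,
                          distortion = list(sfbg = 0.7, sfsig = 0.8,
                                            alpha = 1.1, beta = -0.3),
                          diff_fold = 4, noise_sd = 0.05, background = 2,
                          peak_height_meanlog = log(30),
                          peak_height_sdlog = 0.4, peak_sd = 150,
                          signal_halfwidth = 200, bin_size = 50,
                          pseudocount = 1, seed = 1,
                          outdir = tempfile("simpair")) {
  stopifnot(distortion$alpha > 0, distortion$sfbg > 0, distortion$sfsig > 0,
            n_diff <= n_candidates, n_outlier_refs <= n_refs)
  set.seed(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # --- site layout: jittered sequential slots, refs wide / candidates narrow
  ref_slot <- 10000; cand_slot <- 2000; margin <- 5000
  n_chrom <- length(chrom_sizes)
  kind <- sample(c(rep("ref", n_refs), rep("cand", n_candidates)))
  chrom_of <- rep(names(chrom_sizes), length.out = length(kind))[
    order(stats::runif(length(kind)))]
  centers <- integer(length(kind))
  for (ch in names(chrom_sizes)) {
    idx <- which(chrom_of == ch)
    slots <- ifelse(kind[idx] == "ref", ref_slot, cand_slot)
    need <- 2 * margin + sum(slots)
    if (need > chrom_sizes[[ch]]) {
      stop("chromosome ", ch, " too small for requested sites (need ",
           need, " bp, have ", chrom_sizes[[ch]], ")")
    }
    cursor <- margin
    for (j in seq_along(idx)) {
      jit <- round(stats::runif(1, -0.1, 0.1) * slots[j])
      # snap to a bin boundary so analysis windows align with track bins
      centers[idx[j]] <- as.integer(round((cursor + slots[j] / 2 + jit) /
                                            bin_size) * bin_size)
      cursor <- cursor + slots[j]
    }
  }
  ref_idx <- which(kind == "ref")
  cand_idx <- which(kind == "cand")
  heights <- stats::rlnorm(length(kind), peak_height_meanlog, peak_height_sdlog)

  # planted biology: differential candidates and violated reference sites
  diff_sel <- if (n_diff > 0) sort(sample(seq_along(cand_idx), n_diff)) else integer(0)
  cand_fold <- rep(1, length(cand_idx))
  if (n_diff > 0) {
    cand_fold[diff_sel] <- rep_len(c(diff_fold, 1 / diff_fold), n_diff)
  }
  out_sel <- if (n_outlier_refs > 0) sort(sample(seq_along(ref_idx), n_outlier_refs)) else integer(0)
  ref_fold <- rep(1, length(ref_idx))
  if (n_outlier_refs > 0) ref_fold[out_sel] <- rep_len(c(5, 0.2), n_outlier_refs)
  fold_of <- rep(1, length(kind))
  fold_of[cand_idx] <- cand_fold
  fold_of[ref_idx] <- ref_fold

  # --- latent per-bin signal (control scale), then inverse-distorted target
  c0 <- pseudocount
  invmap <- function(v) {
    (2^((log2(v + c0) - distortion$beta) / distortion$alpha) - c0) /
      distortion$sfsig
  }
  # background/signal boundary of the applied distortion: where the two
  # inverse branches coincide (invmap(v) = v / sfbg) the switch is seamless,
  # so bins near the cutoff are insensitive to which branch fires -- the
  # same property the forward two-tier map has at its own boundary.  If the
  # branches never cross, fall back to the log2 midpoint between background
  # and a typical peak top.
  bg_t <- background / distortion$sfbg
  vs <- seq(background * 0.2,
            background + exp(peak_height_meanlog + 2 * peak_height_sdlog),
            length.out = 4000)
  fdiff <- invmap(vs) - vs / distortion$sfbg
  if (max(abs(fdiff)) < 1e-9) {
    thr <- background  # identity distortion: branches agree everywhere
  } else {
    flips <- which(fdiff[-length(fdiff)] * fdiff[-1] <= 0 &
                     abs(fdiff[-length(fdiff)]) + abs(fdiff[-1]) > 0)
    thr <- if (length(flips)) {
      vs[flips[which.min(abs(vs[flips] - background))]]
    } else {
      2^((log2(background + c0) +
            log2(background + exp(peak_height_meanlog) + c0)) / 2) - c0
    }
  }
  # pure background bins must always take the background branch, or sfbg
  # would not be the realized background ratio
  thr <- max(thr, background * 1.001)
  footprint <- 4 * peak_sd  # beyond this the Gaussian is < 0.04% of height

  bins <- bin_genome(chrom_sizes, bin_size)
  ctrl_vals <- tgt_vals <- numeric(length(bins))
  bin_chrom <- as.character(GenomicRanges::seqnames(bins))
  # noiseless central-window means per site, both samples
  site_mean_control <- site_mean_target <- numeric(length(kind))
  for (ch in names(chrom_sizes)) {
    sel <- which(bin_chrom == ch)
    bc <- (GenomicRanges::start(bins)[sel] - 1 +
             GenomicRanges::end(bins)[sel]) / 2
    ctrl_lat <- tgt_ctrl_scale <- rep(background, length(sel))
    for (j in which(chrom_of == ch)) {
      span <- which(abs(bc - centers[j]) <= footprint)
      p <- heights[j] * exp(-((bc[span] - centers[j])^2) / (2 * peak_sd^2))
      ctrl_lat[span] <- ctrl_lat[span] + p
      tgt_ctrl_scale[span] <- tgt_ctrl_scale[span] + fold_of[j] * p
    }
    # per-bin inverse of the two-tier map: bins above the boundary pass
    # through the inverse signal map, the rest are divided by sfbg
    tgt_lat <- ifelse(tgt_ctrl_scale > thr, invmap(tgt_ctrl_scale),
                      tgt_ctrl_scale / distortion$sfbg)
    for (j in which(chrom_of == ch)) {
      central <- which(abs(bc - centers[j]) <= signal_halfwidth)
      site_mean_control[j] <- mean(ctrl_lat[central])
      site_mean_target[j] <- mean(tgt_lat[central])
    }
    ctrl_vals[sel] <- ctrl_lat
    tgt_vals[sel] <- tgt_lat
  }
  if (noise_sd > 0) {
    mlog <- -noise_sd^2 / 2  # unit-mean multiplicative noise
    ctrl_vals <- ctrl_vals * stats::rlnorm(length(ctrl_vals), mlog, noise_sd)
    tgt_vals <- tgt_vals * stats::rlnorm(length(tgt_vals), mlog, noise_sd)
  }

  # --- write files
  files <- list(control = file.path(outdir, "control.bw"),
                target = file.path(outdir, "target.bw"),
                refs = file.path(outdir, "refs.bed"),
                candidates = file.path(outdir, "candidates.bed"),
                chrom_sizes = file.path(outdir, "chrom.sizes"))
  write_track(bins, ctrl_vals, chrom_sizes, files$control)
  write_track(bins, tgt_vals, chrom_sizes, files$target)
  refs_gr <- GenomicRanges::GRanges(
    chrom_of[ref_idx],
    IRanges::IRanges(start = centers[ref_idx] - 99, width = 200),
    name = sprintf("ref_%d", seq_along(ref_idx)))
  cand_gr <- GenomicRanges::GRanges(
    chrom_of[cand_idx],
    IRanges::IRanges(start = centers[cand_idx] - 249, width = 500),
    name = sprintf("cand_%d", seq_along(cand_idx)))
  write_regions(refs_gr, files$refs)
  write_regions(cand_gr, files$candidates)
  writeLines(paste(names(chrom_sizes), format(chrom_sizes, scientific = FALSE),
                   sep = "\t"), files$chrom_sizes)

  # The (sfsig, alpha, beta) triple is nearly redundant: rescaling sfsig can
  # be absorbed into alpha/beta, so the raw distortion inputs are not the
  # quantities the estimation convention identifies.  The recorded truth is
  # therefore the distortion re-expressed in the canonical parameterization
  # (sfsig = background-subtracted central-mean ratio over the genuine
  # reference sites; alpha/beta = the log2 moment-matching coefficients of
  # the sfsig-scaled values), computed from the noiseless latent site means.
  honest <- ref_idx[!(seq_along(ref_idx) %in% out_sel)]
  x_h <- site_mean_control[honest]
  y_h <- site_mean_target[honest]
  sfsig_canon <- mean(x_h - background) / (mean(y_h) - bg_t)
  lx <- log2(x_h + c0)
  ly <- log2(sfsig_canon * y_h + c0)
  alpha_canon <- stats::sd(lx) / stats::sd(ly)
  beta_canon <- mean(lx) - alpha_canon * mean(ly)

  truth <- list(true_sfbg = distortion$sfbg, true_sfsig = sfsig_canon,
                true_alpha = alpha_canon, true_beta = beta_canon,
                distortion_input = distortion,
                site_mean_control = site_mean_control,
                candidates = data.frame(
                  chrom = chrom_of[cand_idx],
                  start = centers[cand_idx] - 250L,
                  end = centers[cand_idx] + 250L,
                  name = sprintf("cand_%d", seq_along(cand_idx)),
                  true_fold = cand_fold),
                reference_sites = refs_gr,
                planted_outlier_sites = out_sel,
                seed = seed)
  c(files, list(truth = truth, bins = bins,
                control_values = ctrl_vals, target_values = tgt_vals))
}

#' Simulate paired spike-in tracks with a known depth ratio
#'
#' The control spike-in track is background plus peaks at spike-in reference
#' sites; the target is the same latent signal multiplied by `depth_ratio`
#' (so total target signal / total control signal = `depth_ratio`), with
#' independent lognormal noise. [spikein_ratio_factor()] on the two totals
#' then returns `1 / depth_ratio`.
#'
#' @param depth_ratio Target/control total-signal ratio.
#' @param chrom_sizes Spike-in genome (default one 500 kb chromosome).
#' @param n_refs Number of spike-in reference sites.
#' @param noise_sd Sdlog of multiplicative noise.
#' @param seed Integer seed.
#' @param outdir Output directory for `spikein_control.bw`,
#'   `spikein_target.bw`, `spikein_refs.bed`.
#' @return List of file paths plus `truth` (`depth_ratio`, totals, seed).
#' @export
simulate_spikein <- function(depth_ratio = 1,
                             chrom_sizes = c(spk1 = 5e5), n_refs = 30,
                             noise_sd = 0.05, seed = 1,
                             outdir = tempfile("simspike")) {
  stopifnot(depth_ratio > 0)
  set.seed(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bin_size <- 50; background <- 2; peak_sd <- 150; margin <- 5000
  slot <- (sum(chrom_sizes) - 2 * margin * length(chrom_sizes)) / n_refs
  if (slot < 2000) stop("spike-in genome too small for ", n_refs, " sites")
  bins <- bin_genome(chrom_sizes, bin_size)
  bin_chrom <- as.character(GenomicRanges::seqnames(bins))
  chrom_of <- rep(names(chrom_sizes), length.out = n_refs)
  centers <- integer(n_refs)
  for (ch in names(chrom_sizes)) {
    idx <- which(chrom_of == ch)
    centers[idx] <- as.integer(margin + (seq_along(idx) - 0.5) * slot +
                                 round(stats::runif(length(idx), -0.1, 0.1) * slot))
  }
  heights <- stats::rlnorm(n_refs, log(30), 0.4)
  vals <- numeric(length(bins))
  for (ch in names(chrom_sizes)) {
    sel <- which(bin_chrom == ch)
    bc <- (GenomicRanges::start(bins)[sel] - 1 +
             GenomicRanges::end(bins)[sel]) / 2
    v <- rep(background, length(sel))
    for (j in which(chrom_of == ch)) {
      span <- which(abs(bc - centers[j]) <= 5 * peak_sd)
      v[span] <- v[span] + heights[j] *
        exp(-((bc[span] - centers[j])^2) / (2 * peak_sd^2))
    }
    vals[sel] <- v
  }
  mlog <- -noise_sd^2 / 2
  noise <- function(n) if (noise_sd > 0) stats::rlnorm(n, mlog, noise_sd) else 1
  ctrl_vals <- vals * noise(length(vals))
  tgt_vals <- vals * depth_ratio * noise(length(vals))
  files <- list(control = file.path(outdir, "spikein_control.bw"),
                target = file.path(outdir, "spikein_target.bw"),
                refs = file.path(outdir, "spikein_refs.bed"))
  write_track(bins, ctrl_vals, chrom_sizes, files$control)
  write_track(bins, tgt_vals, chrom_sizes, files$target)
  refs_gr <- GenomicRanges::GRanges(
    chrom_of, IRanges::IRanges(start = centers - 99, width = 200),
    name = sprintf("spk_%d", seq_len(n_refs)))
  write_regions(refs_gr, files$refs)
  bw <- bin_size
  c(files, list(truth = list(
    depth_ratio = depth_ratio,
    control_total = sum(ctrl_vals) * bw,
    target_total = sum(tgt_vals) * bw,
    reference_sites = refs_gr, seed = seed)))
}

#' Total signal of a track
#'
#' Sum of per-base values over all chromosomes; the track-level "count" used
#' for spike-in ratio scaling.
#'
#' @param track BigWig path or `RleList`.
#' @return A single number.
#' @export
track_total <- function(track) {
  rl <- read_track(track)
  sum(vapply(rl, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                   S4Vectors::runLength(r)), numeric(1)))
}
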