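#' Mean signal per region in two tracks
#'
#' @param control_track,target_track BigWig paths or `RleList`s.
#' @param regions `GRanges` of candidate regions.
#' @return A data.frame with `value_control` and `value_target` per region
#'   (mean track value over `[start, end)`, missing data counting as 0).
#' @export
quantify_regions <- function(control_track, target_track, regions) {
  data.frame(value_control = region_means(control_track, regions),
             value_target = region_means(target_track, regions))
}

#' Fold-change direction call
#'
#' Pseudocounted linear ratios with an inclusive threshold: a region is `up`
#' when `(target + c) / (control + c) >= fc_cutoff`, `down` when the inverse
#' ratio reaches the cutoff, otherwise `unchanged`.
#'
#' @param value_control,value_target Per-region mean values.
#' @param fc_cutoff Threshold ratio, >= 1.
#' @param pseudocount Pseudocount `c`.
#' @return Character vector in `{up, down, unchanged}`.
#' @export
fold_change_call <- function(value_control, value_target, fc_cutoff = 2,
                             pseudocount = 1) {
  stopifnot(fc_cutoff >= 1, length(value_control) == length(value_target))
  r <- (value_target + pseudocount) / (value_control + pseudocount)
  ifelse(r >= fc_cutoff, "up",
         ifelse(1 / r >= fc_cutoff, "down", "unchanged"))
}

#' Two-sided exact Poisson test for paired region counts
#'
#' Tests whether the target count is consistent with a Poisson rate set by
#' the control: `lambda = exposure_ratio * max(count_control, pseudo_floor)`.
#' The two-sided p-value is `2 * min(P[X <= k], P[X >= k])` capped at 1,
#' with `k` the rounded target count. Vectorized over regions.
#'
#' @param count_control,count_target Non-negative counts (rounded to
#'   integers internally).
#' @param exposure_ratio Positive ratio adjusting for residual depth
#'   differences (1 after normalization).
#' @param pseudo_floor Minimum rate, so zero-control regions stay testable.
#' @return P-values in `[0, 1]`.
#' @export
poisson_test <- function(count_control, count_target, exposure_ratio = 1,
                         pseudo_floor = 1) {
  if (exposure_ratio <= 0) stop("exposure_ratio must be > 0")
  stopifnot(all(count_control >= 0), all(count_target >= 0))
  lambda <- exposure_ratio * pmax(round(count_control), pseudo_floor)
  k <- round(count_target)
  lower <- stats::ppois(k, lambda)
  upper <- stats::ppois(k - 1, lambda, lower.tail = FALSE)  # P[X >= k]
  pmin(2 * pmin(lower, upper), 1)
}

#' Call differential regions between two normalized tracks
#'
#' Quantifies both tracks over candidate regions, computes M/A/fold change,
#' applies the configured statistic and writes the calls table, an MA plot
#' and up/down/unchanged BED files.
#'
#' Statistics: `"fc"` calls by fold change alone; `"poisson"` by the exact
#' Poisson test (region means are converted to counts by multiplying by the
#' region width in `bin_size` units, since tracks store densities); `"both"`
#' (default) requires both to pass. With `adjust = TRUE` Poisson p-values are
#' Benjamini-Hochberg adjusted across regions and compared to `q`.
#'
#' @param control_track,target_track BigWig paths or `RleList`s (normally
#'   the control and the normalized target).
#' @param regions Candidate regions: BED path or `GRanges`.
#' @param config Configuration list (see [default_config()]: `stat`,
#'   `fc_cutoff`, `q`, `adjust`, `pseudocount`, `bin_size`).
#' @param outdir Optional output directory for `calls.tsv`, `ma.png`,
#'   `up.bed`, `down.bed`, `unchanged.bed` (BED6, score = M x 100 clamped to
#'   \[0, 1000\]).
#' @return A data.frame of class `tiernorm_calls` with columns `chrom`,
#'   `start`, `end`, `name`, `value_control`, `value_target`, `M`, `A`,
#'   `fold_change`, `p_value`, `p_adj`, `direction`, `significant`.
#' @export
call_differential <- function(control_track, target_track, regions,
                              config = default_config(), outdir = NULL) {
  config <- utils::modifyList(default_config(), config)
  stat <- match.arg(config$stat, c("both", "fc", "poisson"))
  regions <- if (is.character(regions)) read_regions(regions) else regions
  c0 <- config$pseudocount
  if (length(regions) == 0L) {
    calls <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        value_control = numeric(0), value_target = numeric(0),
                        M = numeric(0), A = numeric(0),
                        fold_change = numeric(0), p_value = numeric(0),
                        p_adj = numeric(0), direction = character(0),
                        significant = logical(0))
  } else {
    vals <- quantify_regions(control_track, target_track, regions)
    ma <- ma_transform(vals$value_control, vals$value_target, c0)
    fc <- (vals$value_target + c0) / (vals$value_control + c0)
    # density -> approximate counts: mean signal times region width in bins
    nb <- pmax(GenomicRanges::width(regions) / config$bin_size, 1)
    p <- poisson_test(vals$value_control * nb, vals$value_target * nb)
    p_adj <- if (config$adjust) stats::p.adjust(p, method = "BH") else p
    fc_dir <- fold_change_call(vals$value_control, vals$value_target,
                               config$fc_cutoff, c0)
    pois_sig <- p_adj <= config$q
    significant <- switch(stat,
                          fc = fc_dir != "unchanged",
                          poisson = pois_sig,
                          both = fc_dir != "unchanged" & pois_sig)
    direction <- ifelse(!significant, "unchanged",
                        ifelse(ma$M > 0, "up", "down"))
    nm <- if (!is.null(regions$name)) as.character(regions$name) else
      paste0("region_", seq_along(regions))
    nm[is.na(nm)] <- paste0("region_", which(is.na(nm)))
    calls <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(regions)),
      start = GenomicRanges::start(regions) - 1L,
      end = GenomicRanges::end(regions),
      name = nm,
      value_control = vals$value_control, value_target = vals$value_target,
      M = ma$M, A = ma$A, fold_change = fc, p_value = p, p_adj = p_adj,
      direction = direction, significant = significant)
  }
  files <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files$calls <- file.path(outdir, "calls.tsv")
    utils::write.table(calls, files$calls, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (nrow(calls)) {
      files$ma <- plot_ma(calls, which(calls$significant),
                          file.path(outdir, "ma.png"),
                          main = "Differential regions (M-A)")
    }
    for (d in c("up", "down", "unchanged")) {
      sel <- calls$direction == d
      gr <- GenomicRanges::GRanges(calls$chrom[sel],
                                   IRanges::IRanges(calls$start[sel] + 1L,
                                                    calls$end[sel]),
                                   name = calls$name[sel])
      files[[d]] <- write_regions(gr, file.path(outdir, paste0(d, ".bed")),
                                  score = calls$M[sel] * 100)
    }
    message(sprintf("differential calls: %d up, %d down, %d unchanged",
                    sum(calls$direction == "up"),
                    sum(calls$direction == "down"),
                    sum(calls$direction == "unchanged")))
  }
  attr(calls, "files") <- files
  class(calls) <- c("tiernorm_calls", class(calls))
  calls
}
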