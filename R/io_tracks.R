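#' Read a BED3/BED6 region file
#'
#' Parses a tab-separated BED file into a [GenomicRanges::GRanges] object.
#' Input coordinates are 0-based half-open (the BED convention); the returned
#' `GRanges` uses the usual 1-based closed convention, so a BED line
#' `chr1 100 200` becomes `chr1:101-200`. Extra columns are mapped to
#' `name` (column 4) and strand (column 6) when present.
#'
#' @param path Path to a BED file with at least three tab-separated columns.
#' @return A `GRanges` with one range per input line, in file order, with a
#'   `name` metadata column (NA where absent).
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(name = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0))
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], ": non-integer coordinates")
  }
  bad <- which(start0 < 0 | end0 <= start0)
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], ": end <= start or negative start")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  character(1)), NA_character_)
  strand <- rep(".", length(fields))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, character(1), 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1, end = end0),
                         strand = strand, name = name)
}

#' Write regions as BED
#'
#' Writes a `GRanges` to BED (0-based half-open). If a numeric `score` column
#' is requested it is clamped to \[0, 1000\] as BED requires.
#'
#' @param regions A `GRanges`; `name` and `score` metadata columns are used
#'   for BED columns 4-5 when present.
#' @param path Output path.
#' @param score Optional numeric vector overriding the score column.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, score = NULL) {
  n <- length(regions)
  nm <- if (!is.null(regions$name)) as.character(regions$name) else rep(".", n)
  nm[is.na(nm)] <- "."
  sc <- if (!is.null(score)) score else if (!is.null(regions$score)) regions$score else rep(0, n)
  sc <- pmin(pmax(round(sc), 0), 1000)
  st <- as.character(GenomicRanges::strand(regions))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions),
                   name = nm, score = sc, strand = st)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path Path to a `chrom.sizes`-style file: chromosome name and length
#'   in bp, tab-separated.
#' @return A named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length < 1)) stop("chromosome lengths must be >= 1")
  stats::setNames(df$length, df$chrom)
}

#' Load a coverage track as a per-chromosome run-length list
#'
#' Reads a BigWig file into an `RleList` of per-base values; regions with no
#' data are 0, matching coverage-track semantics. An `RleList` passed in is
#' returned unchanged, so pipeline functions accept either form.
#'
#' @param track Path to a BigWig file, or an `RleList`.
#' @return An `RleList` of per-base signal.
#' @export
read_track <- function(track) {
  if (methods::is(track, "RleList")) return(track)
  if (!file.exists(track)) stop("track file not found: ", track)
  rl <- rtracklayer::import(track, as = "RleList")
  # NaN can occur in malformed tracks; treat as 0 coverage
  has_na <- vapply(rl, function(r) anyNA(S4Vectors::runValue(r)), logical(1))
  if (any(has_na)) {
    for (ch in names(rl)[has_na]) {
      v <- S4Vectors::runValue(rl[[ch]])
      v[is.na(v)] <- 0
      S4Vectors::runValue(rl[[ch]]) <- v
    }
    message("NA/NaN track values set to 0 on: ",
            paste(names(rl)[has_na], collapse = ", "))
  }
  rl
}

#' Tile a genome into fixed-width bins
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp; the last bin of each chromosome may be
#'   shorter.
#' @return A `GRanges` of non-overlapping, sorted tiles jointly covering each
#'   chromosome.
#' @export
bin_genome <- function(chrom_sizes, bin_size) {
  stopifnot(bin_size >= 1, all(chrom_sizes >= 1))
  starts <- lapply(chrom_sizes, function(len) seq.int(1L, len, by = bin_size))
  n_per <- lengths(starts)
  starts <- unlist(starts, use.names = FALSE)
  lens <- rep(unname(chrom_sizes), n_per)
  gr <- GenomicRanges::GRanges(
    S4Vectors::Rle(factor(names(chrom_sizes), levels = names(chrom_sizes)),
                   n_per),
    IRanges::IRanges(start = starts, end = pmin(starts + bin_size - 1, lens)))
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Mean track value per genome bin
#'
#' @param track BigWig path or `RleList`.
#' @param bins A `GRanges` of tiles from [bin_genome()].
#' @return Numeric vector of per-bin mean signal, one per tile.
#' @export
bin_track <- function(track, bins) {
  rl <- read_track(track)
  .check_chroms(bins, rl)
  rl <- rl[GenomeInfoDb::seqlevels(bins)]
  GenomicRanges::binnedAverage(bins, rl, "score")$score
}

.check_chroms <- function(regions, rl) {
  want <- unique(as.character(GenomicRanges::seqnames(regions)))
  missing <- setdiff(want, names(rl))
  if (length(missing)) {
    stop("chromosome(s) absent from track: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Extract a per-region, per-bin signal matrix around region centers
#'
#' For each region the window `center - flank .. center + flank` is divided
#' into `n_bins` equal-width bins and the mean track value in each bin is
#' returned. Rows on the `-` strand are reversed so all rows share the same
#' orientation. Bins extending past a chromosome end are set to 0 and counted.
#'
#' @param track BigWig path or `RleList`.
#' @param regions `GRanges` of reference or candidate sites; the window is
#'   anchored at each region's midpoint.
#' @param n_bins Number of bins across the window.
#' @param flank Half-window width in bp; `2 * flank` must be a multiple of
#'   `n_bins`.
#' @return A numeric matrix (regions x bins) with attributes `bin_size`
#'   (bp per bin) and `flank`.
#' @export
extract_signal <- function(track, regions, n_bins = 40L, flank = 1000L) {
  stopifnot(n_bins >= 1, flank >= 1)
  if ((2 * flank) %% n_bins != 0) {
    stop("2*flank (", 2 * flank, ") must be a multiple of n_bins (", n_bins, ")")
  }
  rl <- read_track(track)
  .check_chroms(regions, rl)
  bw <- (2 * flank) %/% n_bins
  centers <- floor((GenomicRanges::start(regions) - 1 +
                      GenomicRanges::end(regions)) / 2)  # 0-based center
  chrom <- as.character(GenomicRanges::seqnames(regions))
  out <- matrix(0, nrow = length(regions), ncol = n_bins)
  n_clipped <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    r <- rl[[ch]]
    len <- length(r)
    # bin j of region i spans 0-based [center - flank + (j-1)*bw, ... + bw)
    bin_start0 <- rep(centers[idx] - flank, each = n_bins) +
      rep.int(seq_len(n_bins) - 1L, length(idx)) * bw
    ok <- bin_start0 >= 0 & (bin_start0 + bw) <= len
    n_clipped <- n_clipped + sum(!ok)
    if (any(ok)) {
      v <- IRanges::Views(r, start = bin_start0[ok] + 1L, width = bw)
      vals <- numeric(length(ok))
      vals[ok] <- IRanges::viewMeans(v)
      out[idx, ] <- matrix(vals, ncol = n_bins, byrow = TRUE)
    }
  }
  if (n_clipped > 0) {
    message(n_clipped, " bin(s) beyond chromosome ends set to 0")
  }
  rev_rows <- which(as.character(GenomicRanges::strand(regions)) == "-")
  if (length(rev_rows)) {
    out[rev_rows, ] <- out[rev_rows, n_bins:1, drop = FALSE]
  }
  structure(out, bin_size = bw, flank = flank)
}

#' Column-wise mean profile of a signal matrix
#'
#' @param mat A regions x bins matrix from [extract_signal()]; `NA` cells
#'   (masked bins) are skipped.
#' @return Numeric vector of per-bin means across regions.
#' @export
aggregate_profile <- function(mat) {
  if (is.null(dim(mat)) || nrow(mat) == 0L) stop("empty signal matrix")
  colMeans(mat, na.rm = TRUE)
}

#' Write per-bin values as a BigWig track
#'
#' @param bins `GRanges` of genome tiles (from [bin_genome()]).
#' @param values Numeric vector, one finite non-negative value per bin.
#' @param chrom_sizes Named chromosome lengths used for the BigWig header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(bins, values, chrom_sizes, path) {
  if (length(values) != length(bins)) stop("one value per bin required")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("track values must be finite and >= 0")
  }
  gr <- bins
  gr$score <- values
  GenomeInfoDb::seqlengths(gr) <-
    chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export.bw(gr, path)
  invisible(path)
}

#' Mean normalized signal over arbitrary regions in one track
#'
#' @param track BigWig path or `RleList`.
#' @param regions `GRanges` of regions to quantify.
#' @return Numeric vector of per-region mean track values (missing data = 0).
#' @export
region_means <- function(track, regions) {
  rl <- read_track(track)
  .check_chroms(regions, rl)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  out <- numeric(length(regions))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    r <- rl[[ch]]
    len <- length(r)
    s <- pmax(GenomicRanges::start(regions)[idx], 1L)
    e <- pmin(GenomicRanges::end(regions)[idx], len)
    keep <- s <= e
    if (any(keep)) {
      v <- IRanges::Views(r, start = s[keep], end = e[keep])
      # mean over the full requested width, absent bases counting as 0
      out[idx[keep]] <- IRanges::viewSums(v) /
        GenomicRanges::width(regions)[idx][keep]
    }
  }
  out
}
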