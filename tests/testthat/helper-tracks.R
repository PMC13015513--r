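# In-memory track builders: pipeline functions accept RleList directly, so
# most unit tests never touch disk.

# per-base values -> RleList track
make_rle <- function(values_by_chrom) {
  methods::as(lapply(values_by_chrom, S4Vectors::Rle), "SimpleRleList")
}

# constant-per-bin track from bin values
make_binned_rle <- function(values_by_chrom, bin_size = 50) {
  make_rle(lapply(values_by_chrom, function(v) rep(v, each = bin_size)))
}

region <- function(chrom, start0, end0, name = NA_character_, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand, name = name)
}

# small, fast synthetic pair shared across tests
small_sim <- function(seed = 1, n_refs = 50, n_candidates = 20, n_diff = 4,
                      n_outlier_refs = 2, ...) {
  simulate_pair(chrom_sizes = c(t1 = 6e5, t2 = 6e5), n_refs = n_refs,
                n_candidates = n_candidates, n_diff = n_diff,
                n_outlier_refs = n_outlier_refs,
                seed = seed, outdir = tempfile("smallsim"), ...)
}
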