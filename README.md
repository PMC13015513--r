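# tiernorm

Cross-sample normalization and differential analysis of epigenomic coverage
tracks (DNase-seq, ATAC-seq, CUT&RUN, MNase-seq, ChIP-seq), anchored on
**stable internal reference regions** such as invariant CTCF binding sites.

## The problem

Coverage tracks from different samples differ in sequencing depth, background
noise and signal-to-noise ratio. Depth scaling (RPM) corrects none of the
latter two, and under global chromatin changes it actively misleads — a
genuine genome-wide loss of signal reappears as an apparent gain elsewhere.
Spike-ins help only when the spike-in material was applied perfectly
consistently, which is hard to verify. Internal reference regions — sites a
user can reasonably assume (and test) to be invariant between samples, e.g.
constitutive CTCF sites overlapping the dataset's peaks — provide an anchor
that experienced the exact same experimental conditions as the regions of
interest.

## The model

Let x be the control sample's signal and y the target's. Genomic bins are
split into **background** and **signal** by a noise cutoff, and the two
tiers are corrected separately:

- background bins: `y' = y * sfbg`, with `sfbg` the ratio of control to
  target background estimated from flanks (2–4 kb) of the reference sites;
- signal bins: `y' = 2^( alpha * log2(y * sfsig + c) + beta ) - c`, where
  `sfsig` is the background-subtracted ratio of the aggregate reference-site
  profiles and `(alpha, beta)` align the sfsig-scaled log2 reference signals
  to the control by moment matching (a z-score map):
  `alpha = sd(x)/sd(y)`, `beta = mean(x) - alpha * mean(y)` in log2 space.

The noise cutoff is the crossing point of the background and signal log2
density estimates. Before any estimation, outlier reference sites are removed
by squared Mahalanobis distance in (M, A) space against a chi-squared(2 df)
quantile (default 0.99). All five parameters — `sfbg`, `sfsig`, `alpha`,
`beta`, `noise` — can be overridden by the user, estimated from spike-in
profiles, or replaced by a single global factor (e.g. a spike-in read-count
ratio).

The differential stage quantifies two tracks over user-supplied regions and
calls changes by an inclusive fold-change threshold (default ≥ 2,
pseudocount 1) and/or a two-sided exact Poisson test with
Benjamini–Hochberg adjustment, writing a calls table, an MA plot and
up/down/unchanged BED files.

## Worked example

Everything below runs offline on simulated data with known ground truth:

```r
library(tiernorm)

sim <- simulate_pair(seed = 7, outdir = "sim")     # control + distorted target
fit <- normalize_track(sim$control, sim$target, sim$refs, outdir = "out")
print(fit$params)
#> Two-tier normalization parameters
#>   sfbg      0.69999  [estimated]
#>   sfsig     0.93199  [estimated]
#>   alpha      1.0957  [estimated]
#>   beta     -0.50704  [estimated]
#>   noise      3.6204  [estimated]

sim$truth[c("true_sfbg", "true_sfsig", "true_alpha", "true_beta")]
#> $true_sfbg   0.7
#> $true_sfsig  0.9302758
#> $true_alpha  1.093698
#> $true_beta   -0.4963972

calls <- call_differential(sim$control, "out/target.norm.bw",
                           sim$candidates, outdir = "out")
table(calls$direction)
#>      down unchanged        up
#>        10        80        10
```

The estimated background factor matches the planted 0.7 to four digits; the
signal-map parameters match the canonical truth within estimation noise; the
20 planted fold-change regions (10 up, 10 down at 4-fold) are all recovered
with no false positives among the 80 null candidates.

The same pipeline is available from a shell:

```sh
inst/scripts/tiernorm normalize --control ctrl.bw --target trt.bw \
    --refs invariant_ctcf.bed -o out/
inst/scripts/tiernorm differential --control ctrl.bw \
    --target out/trt.norm.bw --regions peaks.bed -o out/
```

## Vignette

`vignettes/two-tier-normalization.Rmd` documents the model, the estimation
conventions (including why the signal-map triple is reported in a canonical
parameterization), all tunable parameters, the simulator's design, and known
limitations.
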