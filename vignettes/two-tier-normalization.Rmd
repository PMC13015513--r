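---
title: "Two-tier normalization of epigenomic tracks with internal reference regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier normalization of epigenomic tracks with internal reference regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiernorm)
```

## Motivation and model

Sequencing-based epigenomic assays produce coverage tracks whose overall
scale, background level and signal-to-noise ratio differ between samples for
purely technical reasons. A single depth factor (reads per million) equalizes
none of these independently, and when a perturbation shifts chromatin
globally it produces outright artifacts: the normalization absorbs the
biology. `tiernorm` instead anchors normalization on *internal reference
regions* — genomic sites the analyst assumes, and can check, to be invariant
between the samples (typically constitutive CTCF binding sites intersected
with the dataset's own peaks; transcription start sites of stably expressed
genes are another choice). Because these sites went through the same
experiment as everything else, they capture the technical distortion
directly.

The key observation is that background and signal are distorted differently,
so one factor cannot fix both. The model therefore corrects the two tiers
separately. Writing $x$ for control signal, $y$ for target signal and $c$
for a global pseudocount:

* **Background bins** are rescaled linearly, $y' = y \cdot \mathrm{sfbg}$,
  where $\mathrm{sfbg}$ is the ratio of control to target background level,
  estimated from flanking windows 2–4 kb away from the reference sites
  (after excluding flank bins that overlap another reference site).
* **Signal bins** are first rescaled by $\mathrm{sfsig}$ — the ratio of
  *background-subtracted* central means of the aggregate reference-site
  profiles — and then aligned in log2 space by an affine map:
  $$ y' = 2^{\alpha \log_2(y \cdot \mathrm{sfsig} + c) + \beta} - c , $$
  with $\alpha = \sigma_x / \sigma_y$ and
  $\beta = \bar{x} - \alpha \bar{y}$ computed on the log2-transformed
  per-site reference signals. This is exactly the z-score transformation
  that maps the target's reference-signal distribution onto the control's
  mean and standard deviation; the same two coefficients could equivalently
  be obtained by a linear fit between the two log2 distributions.

Bins are assigned to a tier by a **noise cutoff**: a Gaussian kernel density
(Silverman's bandwidth) is fitted to the background and to the signal log2
samples pooled from both samples (target values pre-scaled by
$\mathrm{sfsig}$), and the cutoff is the first crossing of the two densities
between their modes. If the densities do not cross between the modes the
midpoint of the two means is used, with a message. A bin whose
sfsig-scaled value exceeds the cutoff is signal; ties go to background,
which is deterministic and conservative.

Before any estimation, outlier reference sites — sites that are *not* in
fact invariant — are removed. Per-site mean signals are M-A transformed
($M = \log_2\frac{y+c}{x+c}$, $A$ the average log2 signal) and the squared
Mahalanobis distance of each $(M, A)$ point from the sample mean, under the
sample covariance, is compared to a $\chi^2_2$ quantile (default 0.99).
Statistics are computed in a single pass by default, which keeps the filter
deterministic and order-free; a second pass after removal is available via
`two_pass = TRUE`. If the covariance is singular (e.g. the two tracks are
identical, making every $M$ zero) the filter falls back to independent
per-axis z-scores at the matching two-sided normal quantile.

In total five parameters are estimated — `sfbg`, `sfsig`, `alpha`, `beta`,
`noise` — and each can be individually overridden by the user, estimated
from spike-in material (`spikein_profile_params()` runs the estimation
stages on spike-in tracks and regions), or replaced wholesale by a single
global factor such as a spike-in read-count ratio
(`spikein_ratio_factor()`, applied in `mode = "single-factor"`). A
`mode = "background-only"` applies only `sfbg` to every bin, which suits
assays with modest signal-to-background contrast such as MNase-seq
nucleosome occupancy. The control track is always the anchor and is never
modified; with several targets, each is normalized against the same control
independently.

## Parameters, defaults and rationale

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 50 bp | genome bin width for classification and output |
| `flank` | 1000 bp | half-width of the reference-site profile window |
| `profile_bin` | 50 bp | bin width inside profile windows |
| `signal_frac` | 0.2 | central fraction of the profile window treated as signal (± 200 bp) |
| `flank_inner`, `flank_outer` | 2000, 4000 bp | background flank windows on both sides of each site |
| `pseudocount` | 1 | shared by every log2 operation; keeps zero-coverage sites finite |
| `chi2_quantile` | 0.99 | Mahalanobis outlier cutoff |
| `fc_cutoff` | 2 | differential fold-change threshold, boundary-inclusive |
| `q` | 0.05 | BH-adjusted significance level for the Poisson test |

The ± 1 kb profile window with 50 bp bins matches common practice for
transcription-factor-site aggregate plots; the central 20% covers the
typical accessible-site footprint while leaving the rest of the window as a
visual shoulder. Background flanks start at 2 kb so that even broad peaks do
not leak into the background estimate, and end at 4 kb to stay local to the
site. The signal scale factor subtracts each sample's own background before
taking the ratio — otherwise a pure background shift would contaminate
`sfsig`; `subtract_background = FALSE` restores the raw ratio for users who
prefer it.

Two conventions are worth spelling out because the design was genuinely
open:

* **Which distribution feeds the noise cutoff.** The cutoff is estimated
  from the reference-site windows (flank bins as the background sample,
  central bins as the signal sample), pooling control and sfsig-scaled
  target values. Using reference flanks rather than the whole genome makes
  the cutoff estimable before any genome-wide pass and keeps it anchored to
  the same regions as every other parameter.
* **Identifiability of the signal map.** The triple
  $(\mathrm{sfsig}, \alpha, \beta)$ is nearly redundant: rescaling
  $\mathrm{sfsig}$ can be absorbed into $\alpha$ and $\beta$ almost exactly
  (the pseudocount is the only thing preventing exact absorption). The
  estimation convention — `sfsig` from the background-subtracted profile
  ratio first, then $(\alpha, \beta)$ by moment matching on the
  sfsig-scaled values — is what pins the triple down. Consequently the
  simulator reports its ground truth in this canonical parameterization
  (computed from the noiseless latent site means, independently of the
  pipeline), and the raw distortion inputs are kept alongside as
  `truth$distortion_input`.

## What the simulator emulates

`simulate_pair()` builds a control track as a flat background plus Gaussian
peaks (σ = 150 bp, i.e. roughly a 300 bp-wide accessible site; heights
lognormal) at reference sites and candidate regions, then derives the target
by pushing every bin through the *inverse* of the two-tier map: bins below
the background/signal boundary are divided by `sfbg`, bins above it pass
through the inverse signal map. The boundary is placed where the two inverse
branches coincide ($\mathrm{invmap}(v) = v/\mathrm{sfbg}$, never below the
background level), mirroring the seamless point the forward two-tier map has
at its own cutoff, so that bins near the boundary are insensitive to which
branch fires. Planted fold changes (differential candidates) and planted
reference-site violations (Mahalanobis true positives) are applied to the
latent signal before distortion. Finally both tracks receive independent
multiplicative lognormal noise with unit mean (`noise_sd = 0.05` by
default), emulating the bin-level variability of a deeply sequenced track.

Sites are placed on a jittered slot grid — wide slots (10 kb) for reference
sites so their background flanks stay clear of other peaks, narrow slots
(2 kb) for candidates — which guarantees disjoint placement by construction.
The default genome is two chromosomes of 3 Mb with 400 reference sites and
100 candidates: large enough that the measurement-noise SE of
$(\alpha, \beta)$ (which scales as $1/\sqrt{n_\mathrm{refs}}$, with the
$\beta$ error amplified by the mean log2 signal) stays well inside the
tolerances the test-suite asserts, and small enough that a full simulate +
normalize cycle takes about a second. Real reference sets (invariant CTCF
sites intersected with peaks) contain thousands of sites, so the default is
conservative in the direction that matters.

What the simulator does **not** emulate: read-level sampling (no
FASTQ/BAM), fragment-length or GC biases, chromatin-state-dependent
background structure, replicate-to-replicate biological variability, and
peak-shape asymmetry. Passing tests therefore demonstrate that the
estimation machinery recovers the model's own distortion under realistic
bin-level noise — not that the model captures every artifact of a real
experiment.

## Differential stage

`call_differential()` quantifies the mean signal of both tracks over
user-supplied regions (missing data counts as zero coverage) and computes
M, A, the pseudocounted fold change, and a two-sided exact Poisson p-value.
Since tracks store densities rather than counts, region means are converted
to the count scale by multiplying by the region width in bins and rounding;
the test's rate is the other sample's count times an exposure ratio (1 after
normalization), floored at `pseudo_floor = 1` so empty regions remain
testable, and the two-sided p-value is $2\min(P[X \le k], P[X \ge k])$
capped at 1. P-values are Benjamini–Hochberg adjusted across regions by
default (`adjust = FALSE` restores raw p-values). The default call rule
requires both an inclusive two-fold change and an adjusted Poisson
$p \le 0.05$; `stat = "fc"` or `"poisson"` selects a single statistic.
Overlapping input regions are analyzed exactly as given.

## Numerical choices and degenerate inputs

* One global pseudocount (default 1 track unit) is shared by every log2
  operation, including the simulator's inverse map.
* Ties at the noise cutoff are background; `alpha <= 0` is a hard error
  (it would reverse signal ranking); normalized output is floored at zero.
* Density estimation uses 1024 grid points over the pooled range and linear
  interpolation between the two grid points bracketing the sign change.
* Identical background and signal distributions are an error (the cutoff is
  meaningless; a manual `noise` override is suggested). A signal mode below
  the background mode triggers the midpoint fallback with a message.
* Fewer than 3 reference sites — before or after outlier removal — is an
  error; a constant target reference signal (σ = 0) is an error.
* BED parsing validates coordinates per line and reports the first
  offending line number; chromosome-name mismatches between tracks and
  regions are an error, never silently harmonized.
* NaN values read from a track are treated as zero coverage and counted in
  a message, consistent with coverage semantics.

## Known limitations

* The hard two-branch boundary means bins whose values straddle the
  estimated cutoff can be assigned a different branch than the one the
  distortion actually applied; the induced per-bin error is bounded by the
  local difference between the two branch maps, which vanishes at the
  branch-coincidence point and grows away from it. On default simulations
  the aggregate reference profile is restored within 5% per bin — dominated
  by $2^{\Delta\beta}$ from the $\beta$ estimation error, not by the
  boundary.
* Single-pass Mahalanobis statistics include the outliers themselves in the
  mean and covariance; with a large fraction of violated sites the filter
  loses power (use `two_pass = TRUE`, or a stricter reference list).
* The Poisson test ignores biological replicate variability; it is a
  technical-count test, not a replacement for replicate-aware dispersion
  modeling.
* Normalization assumes the reference sites are genuinely invariant. The
  M-A diagnostic plot (`ma.png`) is the place to check this assumption: a
  reference set drifting coherently with the perturbation shows up as a
  global M offset that the filter cannot remove.

## A complete run

```{r example, eval = FALSE}
sim <- simulate_pair(seed = 7, outdir = "sim")
fit <- normalize_track(sim$control, sim$target, sim$refs, outdir = "out")
print(fit$params)
calls <- call_differential(sim$control, "out/target.norm.bw",
                           sim$candidates, outdir = "out")
table(calls$direction)
```

`out/` then contains the normalized BigWig, `params.tsv` (values and
provenance of the five parameters), `qc.tsv` (background scaling, per-sample
signal-to-noise, outlier counts, distribution summaries), the M-A scatter
with removed sites highlighted, the density-intersection diagnostic, the
differential calls table, the MA plot of candidate regions, and
up/down/unchanged BED files.
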