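---
title: "Models and methods behind imcdenoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind imcdenoise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(imcdenoise)
```

This vignette documents the statistical model, the numerical decisions
and the limits of validation for the package. It states no empirical
result that the test suite does not itself compute.

## Imaging model and assumptions

An IMC channel image is modeled as `R = P[X] + Q`: a clean intensity
field `X` observed through pixel-independent Poisson counting noise,
plus a sparse hot-pixel component `Q` of near-isolated high-count
pixels. Channel spillover is assumed negligible (well-titrated panels)
and is not modeled. Both restoration stages lean on two structural
assumptions about tissue images: local continuity (a genuine pixel has
several neighbors with similar intensity) and the signal-dependence of
Poisson noise (variance equals the mean).

## Stage 1: adaptive hot-pixel detection

The Anscombe transform `2 * sqrt(x + 3/8)` makes Poisson counts
approximately unit-variance, so the eight directional neighbor
differences `d_i` within a 3x3 window become approximately homoscedastic and their
distributions can be summarized by a single robust center `mu_i`
(estimated by the median over valid pixels). The aggregate statistic
sums, per pixel, the `l = 4` signed differences closest to their
centers: for a genuine pixel at least half of its neighbors are assumed
similar, driving the sum toward zero; a hot pixel exceeds *all*
neighbors, so even its four most-typical differences are large and
positive. A pixel adjacent to a hot pixel is protected: the one extreme
(negative) difference it gains is excluded by the `l`-smallest-distance
selection.

The detection threshold is found on a Gaussian-KDE fit of the statistic,
evaluated on a unit-spaced grid: scanning right of the global mode, the
threshold is the first point where either the first derivative has
vanished (the distribution has ended; tolerance `1e-6` of the peak
density) or the second derivative changes from `>= 0` to `<= 0` (the
convex decay of the main lobe gives way to a new concave bump of
outliers). The two criteria are alternatives ("first point satisfying
either"), which is the permissive reading and is what lets a
well-separated outlier bump be cut at the valley rather than beyond it.
If no grid point qualifies, the threshold is `+Inf` and the iteration
flags nothing — this is the normal stopping condition.

**Bandwidth.** The bandwidth is Silverman's rule of thumb
(`stats::bw.nrd0`) **floored at the grid spacing** (1). The floor is a
numerical-soundness requirement, not a tuning parameter: with a sample
standard deviation of ~2 the rule of thumb gives `h ~ 0.25`, and finite
differences of a KDE evaluated at unit spacing then see sampling wiggles
as spurious convex-to-concave flips, flagging ~1% of perfectly normal
pixels in an already-clean iteration. Flooring `h` at the resolution at
which derivatives are read removes the artifact entirely (false-flag
rate drops to ~0 in the zero-density control) while leaving genuinely
separated outlier bumps detectable, since hot-pixel statistics sit many
units beyond the main lobe.

Flagged pixels are replaced by the median of their full 3x3 window
(center included) computed on the pre-replacement image, so replacement
order cannot matter. Detection and replacement run in the Anscombe
domain; only the final image is inverse-transformed (algebraic inverse
`(y/2)^2 - 3/8`; the exact-unbiased inverse is deliberately not
implemented). Outputs are therefore real-valued; `round_output = TRUE`
restores integer counts. Borders are handled by edge replication, so a
corner pixel's "neighbors" partially replicate itself; its aggregate
statistic is attenuated by roughly the fraction of replicated
directions, which slightly lowers sensitivity on the one-pixel border.

Iterating (default 3, with early stopping) lets the peeling of cluster
edges expose interior cluster pixels. Two-pixel clusters are removed
reliably (each member still has 7 informative neighbors); 4x4 and larger
blocks are mostly *not* removed — interior pixels see only hot
neighbors and look locally normal. That asymmetry is by design: large
aggregates are outside this detector's model, and the acceptance suite
asserts both directions.

## Stage 2: self-supervised shot-noise filtering

With hot pixels removed the model reduces to `R = P[X]`, and the
denoising target is `E[X | context]`. Because a tissue section can be
ablated only once, no clean training pairs exist; the network is
trained blind-spot style: 0.2% of the pixels of each 64x64 patch
(exactly 8) are masked — replaced by a uniformly drawn neighbor within
their 5x5 window — and the loss is evaluated *only* at masked pixels,
with the unmasked original patch as the target. Masked pixels are
stratified over an even grid partition of the patch (one per stratum) so
coverage is spatially uniform; masks are re-drawn every epoch to
maximize pixel coverage over training.

The data term is the I-divergence
`sum M_p [r log(r/F) - r + F] / sum M_p` — the Poisson negative
log-likelihood up to constants, hence the statistically matched loss for
count data (its minimizer in `F` is the conditional mean). The
`0 log 0 = 0` convention handles empty pixels; `log` arguments are
floored at `1e-8` as a guard that is provably inert for the softplus
outputs the network produces. The regularizer is a discrete Hessian
norm, `|f_xx| + |f_yy| + 2|f_xy|` averaged over interior pixels
(central second differences; the one-pixel border has no central
stencil and is excluded). It encodes continuity of biological structure
and suppresses the speckle that a pure blind-spot loss leaves behind.
`lambda_Hessian = 3e-6` balances fidelity and smoothness; `0` gives the
unregularized variant. Validation loss includes the regularizer, for
consistency with the optimized objective.

**Architecture.** A residual U-Net with four 2x2 max-pool
down-samplings (hence inference inputs must be padded to multiples of
16; padding replicates border pixels and is cropped after the forward
pass). Each res-block is one 3x3 convolution, batch normalization and
ReLU with an identity shortcut (1x1 projection when the channel count
changes); channel widths double per level from `base_filters`
(reference width 32; the desk-scale tests use 8); the two central
blocks carry 0.5 dropout; decoder levels concatenate the encoder skip
features; the final 1x1 convolution feeds a softplus, so predictions
are strictly positive — which both matches count data and protects the
log in the loss. Patches are percentile-normalized (default 99.99, the
knob exposed as `percentile`; the full-scale range is 99.9-99.999
chosen per dataset) with one shared scale per channel, stored so
predictions are rescaled exactly.

**Training schedule.** Adam, initial learning rate 0.001, batch 128 at
reference scale, 200 epochs, learning rate multiplied by 0.6 when the
validation loss fails to improve for 20 epochs, 85/15 train/validation
split after 8-fold augmentation (three rotations, and mirrors of all
four orientations). All randomness (weights, masks, shuffling, dropout)
derives from one seed; two runs with the same seed produce identical
losses to float precision.

**Implementation note.** No deep-learning framework exists in the
supported environment, so forward/backward passes are implemented in
the package: im2col + single-precision BLAS GEMM convolution kernels
(C++), with the backward input-gradient computed as a convolution with
the flipped transposed kernel and the forward im2col matrix cached for
the weight gradient. Gradients are verified in the test suite against a
double-precision naive convolution oracle and, end-to-end, against
finite differences. Float accumulation (~1e-7 relative) is far below
stochastic-gradient noise.

## The synthetic-data generator

`simulate_imc()` emulates the statistical structure the pipeline
assumes, replacing external reference imagery: a clean field of
anisotropic Gaussian blobs (cell-like) and/or smoothed random-walk
filaments (stroma-like) scaled so the foreground mean hits `lambda_fg`
over a background `lambda_bg` (masks defined by thresholding the
noiseless field at the midpoint, solved by a short fixed-point
iteration since the mask depends on the scaling); independent Poisson
sampling; hot pixels injected at configurable densities as singles and
as 2-4-pixel connected clusters. Injected amplitudes are
`max(local 3x3 max, lambda_fg)` times a uniform 5-20 factor — the
amplitude model is invented (no quantitative description of hot-pixel
intensity exists to copy) and is exposed as a config distribution.
Ground truth (clean field, hot mask, foreground/background masks) ships
with every instance.

What a green test does **not** establish: real IMC backgrounds carry
structured artifacts (ablation streaks, isotope impurity residue) and
real foregrounds have sharper sub-cellular texture than Gaussian blobs;
the simulator's smooth fields make shot-noise removal easier than on,
say, fine reticular stroma. The benchmarks therefore validate the
mechanics and the statistical model, not field performance on any
particular marker.

## Desk-scale benchmark choices

The acceptance benchmarks run on one CPU core in minutes, so they are
scaled down from reference training:

* Hot-pixel benchmark: 10 seeded 256x256 blob images, `lambda_fg 20`,
  `lambda_bg 1`, 1% single hot pixels; recall, false-flag rate and RMSE
  bounds per instance. Baselines are compared at their *tuned* best
  threshold over a grid (10-200 counts), mirroring how such filters are
  deployed.
* Denoising benchmark: `base_filters 8`, 30 epochs, 512 augmented (64 base tiles from 12 simulated images)
  patches, batch 16, 3 independent seeds
  (training and evaluation both reseeded). Two desk-scale parameters
  deserve justification:
  - **`rho = 0.27`.** The background-patch filter discards a patch when
    its zero-pixel fraction exceeds `rho`; the threshold is
    dataset-specific by design (reference range 0.2-0.99). At
    `lambda_bg = 1` a pure-background tile has zero fraction
    `~exp(-1) ~ 0.35`, so a permissive `rho` keeps every tile, ~92% of
    training patches contain no foreground, and the network learns the
    background and nothing else — the precise failure mode the filter
    exists to prevent. `rho` is set at the tile zero-fraction median of
    this generator, which actually separates foreground-bearing tiles.
  - **Batch 16.** The reference batch of 128 is tuned to thousands of
    patches; with ~500 desk patches it yields 4 gradient steps per
    epoch and 30-epoch budgets cannot converge. Batch 16 gives ~32
    steps per epoch at identical cost per epoch.

  The criterion's stated knobs (network width, epochs, patch floor,
  seed count, the 1 dB bar, the generator intensities) are untouched.

## Numerical and edge-case decisions

* Percentiles use linear interpolation between order statistics
  (`quantile` type 7) — dialects differ, so the convention is part of
  the contract.
* Normalized patches are *not* clipped at 1; softplus outputs and the
  I-divergence tolerate values above 1 and clipping would destroy
  bright-signal information. The stored scale makes de-normalization
  exact.
* `stdb()` uses the population (divide-by-N) convention; comparisons
  across methods cancel the convention either way.
* `binarize()` is `>=`-inclusive: with the single-threshold-1
  background cut applied to softplus-positive denoised images the
  boundary case is material.
* Empty-vs-empty masks score F1 = Jaccard = 1 (vacuous agreement);
  empty truth with non-empty prediction scores 0.
* SSIM uses an 11-point Gaussian window (sigma 1.5), K1 = 0.01,
  K2 = 0.03, dynamic range from the image pair unless given.
* KDE threshold scan: derivative tolerance `1e-6 x` peak density; both
  it and the bandwidth floor are exposed as arguments.
* Fewer than 10 valid aggregate samples, or a degenerate (zero-spread)
  sample: detection is skipped for the iteration with a warning rather
  than guessed.
* NTHM/MTHM follow the classical fallback contracts (clip to the
  in-bounds neighbor maximum / replace by the window median when the
  excess exceeds the threshold); replicate borders never let a pixel be
  its own neighbor. The Gaussian baseline defaults to the 5x5,
  sigma 0.8 registry configuration; the sigma-1 variant is reachable
  through the arguments.
* The simulator caps clusters at 4 connected pixels so that both the
  small-cluster capability and the large-cluster limitation are
  exercised.

## Known limitations

* DIMR does not remove large hot-pixel aggregates (4x4 and up); this is
  inherent to the neighbor-difference model and asserted, not hidden,
  by the tests.
* One model per channel is the default; pooling patches across channels
  works (pass several images to `extract_patches()`) but no
  cross-channel weighting is attempted.
* The TIFF codec is deliberately baseline-only (uncompressed grayscale
  uint16/float32, single image); multi-page stacks, RGB and compressed
  files are rejected with descriptive errors rather than half-read.
* Training on CPU in R is minutes-per-small-model, not
  seconds-per-large-model; the architecture is faithful but the
  reference-scale 200-epoch/5000-patch regime is out of desk scope.
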