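# imcdenoise

Two-stage restoration of Imaging Mass Cytometry (IMC) images: adaptive
hot-pixel removal followed by self-supervised shot-noise filtering.

## The problem

IMC records ion counts per 1 µm pixel for 40+ metal-tagged antibody
channels. Two technical noise sources dominate the raw images:

* **Hot pixels** — isolated pixels (or small clusters of a few
  consecutive pixels) with spuriously high counts, uncorrelated with
  tissue structure, putatively from antibody aggregates.
* **Shot noise** — signal-dependent Poisson counting noise inherent to
  ion detection; severe wherever marker expression is low.

The imaging model is

```
R = P[X] + Q
```

with `X` the clean signal, `P[·]` pixelwise Poisson corruption and `Q`
the hot-pixel component (channel spillover is neglected, as is
appropriate for well-titrated panels).

## The method

**Stage 1 — DIMR** (differential intensity map–based restoration).
The image is variance-stabilized with the Anscombe transform
`x ↦ 2√(x + 3/8)` and pixels below a background cut (4, in the
transformed domain) are excluded. For each of the 8 directions of a 3×3
window the difference map `d_i(p) = t(p) − t(neighbor_i(p))` is formed;
`μ̃_i`, the median of each map, is a robust center estimate. Per pixel,
the distances `Δ_i = |d_i − μ̃_i|` are sorted and the `l = 4` signed
differences with smallest `Δ` are summed into the statistic `T_l`: a
normal pixel has several neighbors close to it and lands near 0; a hot
pixel exceeds all neighbors and lands far in the right tail. A Gaussian
KDE is fitted to `T_l` on a unit-spaced grid and the detection threshold
`x_T` is the first grid point right of the mode where either the
derivative has vanished (the distribution has ended) or the curvature
flips from convex to concave (a separate outlier bump begins). Flagged
pixels are replaced by their 3×3 median; the procedure iterates (default
3×, stopping early when nothing is flagged) and the result is mapped
back with the algebraic inverse `(y/2)² − 3/8`. No user-set intensity
threshold is involved.

**Stage 2 — DeepSNiF** (deep self-supervised noise filtering).
A residual U-Net (four 2×2 max-pool down-samplings, one conv + batch
norm + ReLU per res-block, concatenating skip connections, softplus
output) is trained blind-spot style on 64×64 patches of the hot-pixel-
removed image: 0.2 % of pixels per patch are masked (replaced by random
5×5 neighbors, stratified over the patch) and the network must predict
their original values from context. The loss is the Poisson
maximum-likelihood-consistent **I-divergence** on masked pixels plus a
**Hessian-norm** regularizer on the whole prediction
(`λ_Hessian = 3e-6`), encoding the spatial continuity of biological
structures:

```
L = Σ_p M_p [ r_p log(r_p / F_p) − r_p + F_p ] / Σ_p M_p
    + λ_H Σ_p ‖R_Hessian(F)‖_p / Σ_p
```

Training uses Adam (lr 0.001, ×0.6 on a 20-epoch validation plateau);
inference pads to multiples of 16 with replicated borders. No clean
reference image is ever needed — the noisy image is its own training
target.

Also included: the NTHM/MTHM threshold baselines and a Gaussian filter;
a synthetic IMC simulator (structured clean fields + Poisson noise +
injected hot pixels with ground-truth masks); metrics (RMSE, PSNR, SSIM,
STDB, CNR, PCC, F1, Jaccard); plain TIFF/CSV/YAML I/O; a CLI.

## Worked example

```r
library(imcdenoise)

# simulate a 256x256 IMC-like channel: blobs at ~20 counts on a
# 1-count background, 1% hot pixels
trip <- simulate_imc(sim_config(size = 256, lambda_fg = 20,
                                lambda_bg = 1,
                                hot_pixel_density = 0.01), seed = 1)
res <- dimr(trip$hot)
print(res$report)
#> hot_pixel_report: 2 iteration(s), 666 pixel(s) flagged (1.0162%)
#>   iter 1: x_T = 17, flagged = 666
#>   iter 2: x_T = Inf, flagged = 0

img_rmse(trip$hot,   trip$noisy)   #> 27.813   (hot pixels in)
img_rmse(res$pixels, trip$noisy)   #> 0.1992   (hot pixels gone)
```

All 666 injected hot pixels were detected (the x_T = 17 threshold was
derived from the data, not set by the user), zero false positives, and
the RMSE against the hot-pixel-free reference drops by two orders of
magnitude. Iteration 2 finds a clean statistic and stops.

Stage 2 on the same kind of data (small network for CPU use):

```r
imgs <- lapply(101:112, function(s)
  simulate_imc(sim_config(size = 256, lambda_fg = 20, lambda_bg = 1,
                          hot_pixel_density = 0), seed = s)$noisy)
ps    <- extract_patches(imgs, rho = 0.27, seed = 1)
model <- deepsnif_train(ps, base_filters = 8, epochs = 30,
                        batch_size = 16, seed = 1)
den   <- deepsnif_predict(model, trip$noisy)
img_psnr(den, trip$clean, max(trip$clean)) -
  img_psnr(trip$noisy, trip$clean, max(trip$clean))
#> ~ +4.9 dB
```

Percentile note: `percentile_normalize()` computes quantiles with linear
interpolation between order statistics (R's default type 7); the scale
is stored so predictions are re-scaled exactly.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "imcdenoise.R", package = "imcdenoise"))')
Rscript $CLI simulate --out sim/ --lambda-fg 20 --lambda-bg 1 --hot-density 0.01 --n 10 --seed 7
Rscript $CLI dimr     --input sim/sim001_hot.tiff --output clean.tiff --report report.json
Rscript $CLI train    --inputs clean.tiff --out model.rds --epochs 30 --base-filters 8
Rscript $CLI predict  --model model.rds --input clean.tiff --output denoised.tiff
Rscript $CLI evaluate --pred denoised.tiff --truth sim/sim001_clean.tiff --metrics rmse,psnr,ssim
Rscript $CLI pipeline --manifest manifest.csv --out out/ [--skip-deepsnif]
```

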