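---
title: "Measuring rice grain moisture from calibrated panicle images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rice grain moisture from calibrated panicle images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricemoist)
```

# The measurement problem

Rice grain moisture content (GMC, percent wet basis: `100 (Wwet −
Wdry)/Wwet`) falls steadily through grain filling, from roughly 50–60% at
the milk stage to under 20% at maturity. Harvest decisions hinge on it:
paddy above 32% is ineligible for purchase programs, and the optimal
harvest sits near 25%. Oven drying, the reference measurement, takes seven
days; resistance and capacitance meters lose accuracy precisely in the
20–40% range where the decision is made. Grain color tracks moisture — wet
grain is green, dry grain yellow to reddish — so a calibrated photograph
of a panicle carries the signal. This package turns that observation into
a measurement pipeline plus a short-horizon forecasting layer.

Valid single-panicle GMC observations are restricted to the closed
interval [13, 60]% (readings outside the physiological range indicate a
failed sample) by `filter_valid()`.

# Color calibration

Outdoor lighting varies shot to shot. Each board photograph carries its
own references: white, black and 18%-gray patches.

* **Contrast stretch** (`contrast_correct`): per channel,
  `Ic = 255 (I − Ibl)/(Iw − Ibl)` using the measured patch means. This
  removes any gain/offset lighting change exactly and brings every image
  to a canonical scale (black patch 0, white patch 255). Values are
  clipped to [0, 255] afterwards; pixels brighter than the white patch
  would otherwise overflow the scale.
* **Gamma solve** (`solve_gamma`): the 18% gray card should read
  (119, 119, 119). From the stretched gray-patch luminance `Ig`, the
  correction `Igm = 255 (Ic/255)^γ` uses
  `γ = ln(119/255)/ln(Ig/255)`. One γ — solved from the patch's gray-level
  (0.299 R + 0.587 G + 0.114 B) — applies to all three channels, keeping
  the correction hue-neutral on the neutral axis. The normalized form of
  the target equation is the only dimensionally consistent reading of the
  gray-card condition.
* **Halation flag** (`halation_mask`): specular glare is bright and
  nearly achromatic, so the per-pixel channel standard deviation
  `σ = sqrt(((R−A)² + (G−A)² + (B−A)²)/3)` separates it from pigmented
  grain. Pixels with σ below 35 are flagged. Flagging happens *after*
  both corrections (the threshold then refers to the canonical scale) and
  is implemented as a mask consulted at aggregation time, not pixel
  deletion, so raster geometry survives for segmentation. Note the flag
  also catches all achromatic board content (velvet, patches, markers) —
  harmless, since those pixels are background anyway.

Corrected pixels are kept as reals until index extraction; re-quantizing
to integers would add a second rounding error for no benefit.

Two properties motivate this design. An affine lighting distortion is
inverted *exactly* by the stretch. A gamma-type distortion is inverted
exactly at the black point, white point and gray card, and approximately
elsewhere; on synthetic boards the residual is small (grain-pixel RMS
about 0.4–1.8 units over the documented distortion ranges, gray card
within 0.1 of 119 — both recomputed by the test suite and
`scripts/acceptance.R`). The synthetic distortion model applies the gamma
warp first and the gain/offset second, in floating point *without*
clipping: real sensors clip, but a clipped white patch destroys the very
reference the stretch needs, so the generator keeps sensor-linear
headroom and the calibration-recovery property is stated on that domain.
A hue side effect remains: under strong gamma distortion the corrected
image's hue can drift a few degrees (three reference points cannot pin an
entire tone curve). The segmentation margins below are therefore stated
for affine-dominant distortions; the calibration recovery property covers
the full gamma range.

# Board geometry and segmentation

Four corner fiducial markers anchor the board. Each is a 12×12-module
square: white backing, black ring, and an 8×8 payload grid encoding the
sampling date and sample code ("YYYYMMDD-ID": 27 date bits, 16 id bits,
8 checksum bits, 13 fixed sync bits). Markers are found as bright blobs
on the dark board (holes filled, so the centroid is rotation-invariant up
to the ±10° the field protocol allows), distinguished from calibration
patches by their interior dark-module fraction, and assigned to image
corners. The four centers fit an affine map from board millimeters to
pixels — adequate for near-normal smartphone shots; a full homography
would only matter at perspective angles the protocol avoids. Payloads are
then sampled on the module grid through that map and validated by
checksum.

`crop_roi` maps a fixed window (board millimeters, configured in the
layout) through the affine fit and resamples nearest-neighbor, excluding
markers and patches by construction. The same index map crops companion
rasters (ground-truth masks, the halation mask) via `crop_apply`.

`remove_background` runs the threshold cascade strictly in the listed
order after halation exclusion:

| stage | removes | rule | default |
|---|---|---|---|
| 1 | rubber band | ExG = 2G − R − B above cut | 150 |
| 2 | card remnants | hue above cut | 60° |
| 3 | shadow / bright card | gray level above cut | 150 |
| 4 | stem | hue below cut | 35° (tunable 25–35) |

The stem cut is exposed rather than automated: stem and immature grain
hues approach each other, and the appropriate value depends on grain
color. Stage counts are recorded and, with the halation count and the
retained pixels, partition the cropped window exactly — an invariant the
tests assert. The cascade is idempotent: re-running it on its own output
changes nothing.

# The eighteen color indices

`pixel_indices` evaluates, per pixel: R, G, B; HSV (H1 in degrees by the
four-branch max/min formula with the achromatic case mapped to 0, S1 =
(x−y)/x with 0 at x = 0, V1 = x); HLS (H2 ≡ H1, L2 = (x+y)/2, S2 by the
two-branch chroma form, the L2 = 0.5 boundary assigned to the lower
branch); L\*a\*b\*; YCbCr (Cr = 0.713 (R−Y) + 128, Cb = 0.564 (B−Y) + 128,
clipped to [0, 255]); and NDI, GI, RGRI.

Scaling conventions matter and are deliberate: HSV, gray level, ExG,
YCbCr and the ratio indices operate on 0–255 channels; HLS and Lab on
[0, 1]-scaled channels (the 0.5 lightness branch point and the 0.008856
cube-root threshold only make sense normalized; the "+128" chroma offsets
only at 0–255).

The Lab transform here is the survey pipeline's linear XYZ
(X = 0.607R + 0.174G + 0.200B, Y = 0.299R + 0.587G + 0.114B,
Z = 0.066G + 1.116B, no white-point division, no R term in Z) — kept
in exactly that linear form; `lab_standard = TRUE` switches to the
conventional sRGB/D65 transform for comparison. Y and the gray level are
the same linear combination and share one routine.

`sample_ci_vector` averages each index arithmetically over retained
pixels (per-pixel-then-average, not index-of-average-color). Hue is
averaged as plain degrees: grain hues live in 35–65°, far from the 0/360
wrap, so circular statistics would change nothing while complicating the
contract. Ratio-index pixels with zero denominators are excluded from
that index's mean and counted, rather than injected as sentinels.

# Feature selection and regression

Features are z-scored with the population (n-denominator) variance —
matching the variance definition used throughout — and decomposed by
eigendecomposition of the correlation matrix, so eigenvalues sum to the
number of variables. Components are retained by the Kaiser rule
(eigenvalue > 1), extended if needed until cumulative explained variance
reaches 90%. Within each retained component, indices with |loading| ≥
0.32 are candidates; redundancy groups then prune exact or deterministic
duplicates: H2 (≡ H1), the ratio family NDI/GI/RGRI when H1 is present on
the same component, and Y/Cr/Cb (affine in R, G, B) when one of R, G, B
is itself selected there. Applied to the reference three-component
loading table this rule returns exactly the eight indices of the reference
calibration (H1, a\*, G, S2, L\*, B, S1, b\*); without the YCbCr group, Cr and
Cb would slip through on the third component. An empty selection lowers
the threshold by 20% steps with a warning.

Four regressors share one interface (`gmc_train` / `predict`):

* **MLR** — ordinary least squares (`lm`).
* **RF** — `randomForest`, 1000 trees.
* **SVR** — `e1071::svm`, RBF kernel, cost 10, ε = 0.1, bandwidth
  `1/(p · mean feature variance)`; cost and ε are exposed since only the
  kernel family is fixed by the method.
* **MLP** — two hidden layers of 30 sigmoid units trained by mini-batch
  RMSProp (η = 0.001, ρ = 0.9, batch 32), written in-package: no
  installed package provides a two-hidden-layer sigmoid network with
  RMSProp. Inputs are min-max scaled to [0, 1] (sigmoid layers saturate
  on raw z-scores), the output layer is linear on min-max-scaled
  responses, and training runs up to 500 epochs with early stopping on a
  10% validation split (patience 50). With a fixed seed and
  single-threaded BLAS the fit is reproducible.

The held-out split (default 20%) is stratified by response decile —
stabilizing the interval-stratified error tables on ~100-row test sets —
with a flag to restore a plain random split; a K = 5 fold assignment over
the training rows is returned alongside. Metrics are RMSE, MAE and MAPE
(zero observations excluded from MAPE with a warning), reported overall
and for true GMC below 40% and below 32% — the intervals that matter for
purchase eligibility. Model comparison is descriptive; no hypothesis
testing is layered on top.

# Multiday decline models and harvest bands

Area-mean series (daily means of twelve 1 m² cuts) are held internally as
fractions; fitted declines and all reports use percentage points. Three
models are provided:

* **Constant daily drop**: the mean of gap-normalized successive
  differences (the regression slope is available as an option);
  prediction `GMC₀ + δ·i`, floored at 0.
* **Constant daily ratio**: the geometric mean of gap-normalized
  day-over-day ratios; prediction `GMC₀ · r^i`. Stating this model as an additive
  moisture *difference* equal to a ratio power would be dimensionally
  inconsistent, so it is implemented as multiplicative decay — the only
  reading under which a daily ratio of 0.969 makes sense.
* **Growth-day logarithmic pair**: `GD = a₁ ln(GMC₀) + b₁` maps the
  current moisture to an effective growth day, and
  `GMC_i = a₂ ln(GD + i) + b₂` predicts forward; defaults are the
  reference coefficients (−40.78, 36.02, −0.514, 2.58), and `fit_gd_log`
  re-estimates both regressions by least squares with their R².

The two logarithmic regressions are *independent fits, not exact
inverses*: with the reference coefficients the i = 0 round trip
reproduces GMC₀ within 0.01 only up to about 0.32; the discrepancy grows
monotonically to 0.0225 at GMC₀ = 0.38. The package states this precisely
in its tests rather than pretending the pair is self-inverse. Forecast
comparisons use `horizon_mae`: for every origin day and horizon i ∈ 1–8,
predict from the observed origin mean and compare at the observed target
day. On noiseless series generated from the logarithmic process itself,
the growth-day model's horizon error is flat while the linear and ratio
models' errors grow with horizon — the qualitative signature that
motivates the growth-day model. With realistic observation noise the
curvature over 8 days (~0.26 points) is smaller than the noise, and the
three models become indistinguishable on short series; the package
demonstrates the shape property on the noiseless process.

Recommendations follow the three-band rule: GMC ≥ 32% inappropriate
(ineligible for purchase), 32% > GMC ≥ 28% appropriate, GMC < 28% most
appropriate.

# What the synthetic data emulates — and what it does not

The generator is first-class, tested code, and every fixture returns its
ground truth.

* **Scenes** (`panicle_scene` / `render_scene`): a 30 × 10 cm board at 2
  px/mm with four payload-carrying markers, the three patches (245/18/119
  with sd 0.5 print noise), and a panicle of ~40 grain ellipses whose hue
  follows GMC, plus stem, rubber band, sample card and a bright shadow.
  Class colors are chosen analytically so that every class clears its
  cascade threshold *and* the halation retention bound with at least
  three noise standard deviations of margin (grain hue is clipped to
  [38.5, 57]°, stem hue drawn from [26, 30.5]°, chroma ≥ 85 so the
  channel σ of pigmented classes stays above 35 after calibration).
  Pixel noise is Gaussian, sd 1.2. Lighting distortion is gamma-then-
  affine in unclipped floats (see above).
* **Hue–GMC law** (`gmc_to_grain_color`): linear,
  `H = 35 + 30 (GMC − 14)/46` degrees over the valid GMC range — wet
  grain greener, dry grain redder — with per-spikelet Gaussian jitter
  (default sd 1.5°). Only the hue *range* and the strength of the
  hue–moisture correlation are empirically grounded; the linear form and
  the chroma/pedestal ranges are the package's own modeling choice, so a
  passing end-to-end test shows the machinery recovers a monotone
  hue-coded signal at realistic noise levels, not that field accuracy
  would match.
* **Feature tables** (`simulate_ci_dataset`): spikelet colors (40 per
  panicle, 30 pixels each, channel noise sd 2) plus per-sample residual
  brightness variation (chroma 88–102, pedestal 28–37 baselines) — field
  photographs retain sample-level lighting differences after calibration,
  and this is what spreads the correlation structure over a brightness
  axis and a hue axis instead of a single dominant component. Colors are
  passed through the same canonical correction the pipeline applies
  (black 0, white 255, gray 119), so simulated features live in the space
  the image pipeline emits; `calibrated = FALSE` keeps raw colors, where
  the hue law is exactly linear (used for the exactness property of the
  linear regressor).
* **GMC populations** (`sample_gmc_population`): shifted log-normals
  truncated by rejection to the observed support, with parameters
  moment-matched by numerical integration to the reference field moments
  — single-panicle mode: mean 29.32, sd 6.98, skewness 1.81 on
  [13.86, 57.43]; area mode: mean 27.15, sd 4.29, skewness 0.57 on
  [20.06, 37.67]. The single-panicle distribution is strongly
  right-tailed (skewness 1.81). The fitted panicle solution places
  its lower bound near 23%, so simulated panicle GMC does not reach the
  observed minimum of 13.86% — the moments, not the extremes, are the
  matching targets.
* **Multiday series** (`simulate_multiday`): the logarithmic process with
  the reference coefficients plus Gaussian noise on the fraction scale,
  daily sampling.

Not emulated: photorealistic texture, awn and leaf clutter, perspective
distortion, the full 24-patch color chart (only white/black/gray are
used), weather-driven dynamics, and cultivar-to-cultivar color
differences. Results on synthetic scenes therefore validate the
*machinery* — calibration algebra, marker geometry, cascade logic, index
arithmetic, model plumbing — not field-transferable accuracy.

# Numerical choices and problem sizes

* Eigenvector signs are fixed (largest-magnitude loading positive) so
  loadings are reproducible; selection uses |loading| only.
* Degenerate inputs fail loudly and early: empty or out-of-bounds patch
  regions, white ≤ black patches, gray patch at 0/255, non-positive
  gamma, empty grain masks, zero-variance feature columns (dropped with a
  warning), series with non-increasing dates.
* The marker decoder thresholds module samples at the midpoint of the
  sampled min/max and validates ring, sync and checksum; a single flipped
  payload bit is rejected.
* Affine fits use least squares on the four marker centers
  (overdetermined by two points, which averages out centroid error).
* Test and acceptance runs use deliberately modest problem sizes — boards
  at 2 px/mm (~616 × 216 px), 4–6 scenes per property, 20 seeded
  distortions, 500-sample feature tables, 100 replicate decline series —
  chosen so the whole suite completes in about a minute while every
  property retains a comfortable margin at those sizes.

# Known limitations

* Three reference patches cannot invert an arbitrary tone curve; hue
  drift of a few degrees persists under strong gamma distortion, which in
  the field argues for the fixed-exposure protocol the board is designed
  around.
* The fixed ROI window assumes the panicle is laid within the grain zone;
  no content-aware cropping is attempted.
* Threshold segmentation is brittle to classes that straddle the fixed
  cuts (e.g., green immature grain versus stem); learned segmentation is
  out of scope here.
* The hue–GMC law is synthetic; absolute accuracies on rendered scenes do
  not transfer to field images, and cross-season or cross-variety
  transfer is explicitly not addressed.
* MLP reproducibility assumes single-threaded numerics; the other three
  models are bit-reproducible under a fixed seed.
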