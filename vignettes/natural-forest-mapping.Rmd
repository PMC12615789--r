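---
title: "Mapping natural forest probability at desk scale: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping natural forest probability at desk scale: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfmap)
```

## The problem

Global tree-cover maps do not distinguish *natural* forest — primary,
naturally regenerating secondary, and managed natural stands — from planted
forests and tree crops. For deforestation monitoring this distinction is the
whole point: a clear-cut in a rubber plantation is a harvest, the same
clear-cut in natural forest is deforestation. `nfmap` implements, end to
end and at a scale that runs on one CPU core, the method behind a
probabilistic natural-forest baseline map: fusing heterogeneous label
sources into training masks, training a multi-modal temporal-spatial vision
transformer (MTSViT) for 8-class semantic segmentation, ensembling,
stitching overlapping inference windows into a seamless probability raster,
calibrating the probabilities, and evaluating the map against a stratified
validation sample with design-based estimators.

Everything is exercised on *synthetic* scenes with the statistical
structure the method assumes, so the full pipeline is testable without any
satellite data download. The synthetic generator is first-class, tested
code, not a fixture.

## Class scheme and label fusion

Each 10 m pixel carries one of nine codes: 0 unknown (never a prediction
target), 1 natural forest, 2 planted forest, 3 tree crops, 4 other
vegetation, 5 built, 6 water, 7 ice/snow, 8 bare/sparse. Classes 2–4 are
the *hard negatives* — spectrally similar to natural forest — and 5–8 the
*soft negatives*.

`assign_classes()` fuses a stack of source layers with ordered rules:

1. The natural-forest candidate set is the union of the natural source
   layers (including a natural-forest probability layer thresholded at
   > 0.5) plus areas burned by wildfire or other natural disturbance with a
   2001–2020 loss year (natural regrowth is assumed).
2. Pixels with permanent-conversion loss (permanent agriculture, hard
   commodities, settlements) or natural-forest probability < 0.3 are
   removed.
3. The result is intersected with the *forest mask*: canopy height
   strictly above 5 m, or natural-disturbance loss, or forest per the
   forest-type layer.
4. Planted forest is its source intersected with the forest mask (planted
   stands must meet the forest definition); tree crops are taken unmasked
   (crops need not).
5. Overlap between the natural candidate set and planted/crop claims is
   irreducibly ambiguous and becomes unknown. The overlap is judged
   against the *pre-removal* candidate set: this keeps fusion monotone —
   marking a pixel as permanently converted can never create a forest
   label, it can only remove one.
6. Other vegetation is assigned conservatively, only where every
   other-vegetation source agrees, year-2000 tree cover is at most 10 %,
   and the forest mask is false.
7. Built, water, ice and bare come from their sources outside the forest
   mask. Noise-induced overlaps among soft negatives resolve by the fixed
   priority water > ice > built > bare > other vegetation (water and ice
   being the most spectrally distinctive); hard-class claims take
   precedence over soft ones.
8. Everything else is unknown.

The 0.5/0.3 probability thresholds and the strict 5 m height cut are fixed
constants of the rule set. With uncorrupted sources the fused raster
reproduces the generator's truth mosaic exactly; the test suite asserts
this idempotence plus the monotone-masking and forest/non-forest
exclusivity invariants under noise.

## Model inputs and the synthetic generator

A training sample is:

* `s2` — four seasonal composites (calendar quarters DJF/MAM/JJA/SON,
  fixed regardless of hemisphere) of 10 surface-reflectance bands
  (B2–B12 order pinned), shape `(4, S, S, 10)`, values in [0, 1];
* `topo` — elevation, slope, aspect, shape `(1, S, S, 3)`. Slope and
  aspect derive from elevation with Horn's 3×3 kernel on the 10 m grid,
  aspect measured clockwise from north, flat pixels assigned slope 0 and
  aspect 0 (the derivative scheme is a package choice; the field has no
  single convention);
* `loc` — the scene center as unit-sphere Cartesian coordinates;
* `labels` — the 0–8 mask.

The generator (`generate_scene()`) draws the class mosaic as a seeded
Voronoi tessellation: seed points are apportioned to classes by the target
area fractions (largest-remainder rule), so realized fractions are
unbiased for the configured ones with a per-scene spread set by the seed
count. Spectra follow class-specific base signatures with a seasonal
phenology cycle whose amplitude is class-dependent (strongest for other
vegetation and tree crops, absent for non-vegetation) and whose phase
peaks in JJA north of the equator and DJF south of it. Planted stands
carry a periodic row texture, tree crops a grid texture, natural forest an
unstructured spatially correlated texture — the spatial signatures the
model's patch tokens can exploit. Reflectance is clipped to [0, 1] after
noise. Water NIR/SWIR reflectance is capped below a configured ceiling.
Source layers are the true class maps corrupted by configured
false-positive/false-negative rates.

What the generator deliberately does **not** emulate: clouds and cloud
shadows (masked upstream in the real pipeline), radiative-transfer
physics, mixed pixels, real geographic layouts, registration error, and
label sources with spatially structured (rather than independent) noise.
Passing tests therefore demonstrate that the machinery is correct under
the stated assumptions, not that the trained toy model would transfer to
real imagery. Residual composite gaps are likewise out of scope: the
generator produces gap-free composites, and a gap-mask hook is left
unimplemented because the upstream handling of partially cloud-free
composites is not specified.

## The MTSViT architecture

Each modality is tokenized independently: every 8×8-pixel patch (4×4 in
the desk preset) is flattened and linearly projected to the embedding
dimension, giving `(S/patch)^2` tokens per image — 256 tokens for a
128×128 scene. Learned spatial positional embeddings are shared across
modalities and time steps; learned temporal embeddings of length 4 index
the seasons, with topography assigned index 1. Both choices follow
standard ViT practice; the source architecture description leaves them
open.

A *shared* spatial encoder (one weight set reused across modalities and
time steps) applies pre-norm transformer blocks over each 256-token
sequence. A *shared* temporal encoder then attends over the time axis
independently per modality and spatial token — a length-4 sequence for
spectra, length-1 for topography. Topography is passed through the
temporal encoder rather than around it so the weight sharing is uniform;
for a length-1 sequence the attention is a fixed mixing step, not a
no-op, but it keeps one code path.

The seasonal embeddings are mean-pooled over time, and the decoder —
plain self-attention blocks — runs over the fused token set: 256 spectral
tokens, 256 topography tokens, and one token from a linear projection of
the location vector. Fusing at the decoder and injecting location as a
single appended token (rather than added to every token) is the package's
reading of the architecture diagram; the mechanism is otherwise
unspecified. The segmentation head is a two-layer MLP (hidden width 768
at full scale) mapping each decoded *spectral* token to
`patch² × 8` values, reshaped to per-pixel logits. No upsampling
convolutions: the head is the simplest faithful reading of "an MLP
predicting pixel-wise class logits".

Default hyperparameters are the full-scale ones: embedding 192, 6 heads,
spatial and temporal depth 2, decoder depth 4, MLP width 768 (about 4.3 M
parameters, pinned in the tests). Inputs are standardized per band with
statistics computed on the training split and stored with the weights.

The forward pass and backpropagation are implemented directly in R on
BLAS matrix operations, with explicit per-layer caches and hand-derived
gradients; the test suite checks every parameter group against central
finite differences. This keeps the package dependency-free and makes the
computation inspectable end to end.

## Training

The loss is masked cross-entropy: unknown pixels contribute nothing, so
the model never learns to predict class 0 but still emits probabilities
there. Augmentation draws one of the four right-angle rotations plus
independent horizontal/vertical flips, applied synchronously to every
band, time step and the labels; right angles avoid resampling. The aspect
band is moved geometrically but its angular values are not recomputed — a
known physical inconsistency of naive augmentation that is accepted
rather than hidden. Train/test splitting happens at the granularity of
square spatial blocks (100×100 km at full scale) so nearby scenes never
straddle the split.

Optimization is Adam (`lr` 1e-3 full scale, weight decay 3e-5 added to
the gradient — the classic Adam semantics, since the recipe does not
specify decoupling — betas 0.9/0.999, eps 1e-8 pinned), with a linear
warmup over the first 10 % of steps, cosine decay to zero afterwards, and
global-norm gradient clipping at 1.0. An ensemble of independently
initialized members (5 at full scale) is trained and predictions are the
arithmetic mean of member softmax outputs — deliberately *not* the
softmax of mean logits, which differs and is pinned against in a
regression test.

### Desk-scale preset

`desk_preset()` fixes the CPU-feasible study conditions used by the
heavier tests and the acceptance script: 30 scenes of 32×32 pixels (24
train, 6 held out) in the high-separation regime (`separation = 1.5`,
iid noise sd 0.005, correlated noise sd 0.01, texture amplitude 0.05),
a reduced MTSViT (embedding 32, 4 heads, depths 1/1/2, MLP 64, 4×4
patches), and a 3-member ensemble trained 50 epochs at peak learning rate
5e-3 with batch 4. The smaller model tolerates — and needs — a higher
peak rate than the full-scale 1e-3; the schedule shape is unchanged.
"High separation" is calibrated by the nearest-centroid property: at
`separation = 1.5` and zero noise, a nearest-centroid classifier on
seasonal band means exceeds 99 % pixel accuracy, which guarantees the
downstream learning check is a test of the training machinery rather
than of class separability. Under these conditions the ensemble reaches
roughly 0.92–0.94 pixel overall accuracy on held-out scenes (the
self-imposed acceptance bar is 0.90), and plot-level evaluation is
typically perfect because the 100-pixel majority vote absorbs scattered
pixel errors.

## Map construction

Full-scale inference runs overlapping 1280 m windows with 210 m between
centers; `stitch()` combines overlapping predictions with weights
`1 / max(d, 5 m)`, where `d` is the Euclidean map distance from the pixel
center to the window center. The 5 m floor (half a pixel) prevents the
singular weight at the center pixel; distance is measured in meters (the
weighting ratio is scale-invariant except through this floor). Stitching
is a convex combination, so values stay within the range of the
contributing tiles, and windows that agree on their overlap stitch with
no seams at all. Window-edge pixels get no extra feathering beyond the
distance weighting. Desk-scale tests may set the stride equal to the
window side for non-overlapping tiling.

Probabilities are quantized to `round(250 p)` (half-to-even), giving a
0.4 % resolution and a worst-case round-trip error of 0.002; the
recommended 0.52 decision threshold is exactly representable as 130.
Tiles persist as 8-bit single-channel TIFFs (values 0–250, nodata 255)
with a JSON sidecar carrying the affine transform, CRS id and nodata
code, and mosaic back losslessly. Calibration is applied before
quantization in the export path.

## Calibration

Deep ensembles remain overconfident; the released full-scale map was
recalibrated with temperature scaling at T = 1.4. `apply_temperature()`
operates on the binary natural-vs-other probability through the logit map
(the released product is this binary probability), with inputs clamped to
[1e-6, 1−1e-6]. `fit_temperature()` minimizes the mean negative
log-likelihood over `log T ∈ [log 0.1, log 10]` by 1-D minimization —
deterministic, with T = 1 returned by convention when all probabilities
are 0.5 and the likelihood is flat. Temperature scaling is strictly
monotone, so rankings and thresholded maps are unchanged up to a
transformed threshold — consistent with calibration leaving the
evaluation metrics at the optimal threshold untouched.

`reliability()` assesses calibration with adaptive histogram binning:
equal-count bins (counts differ by at most one) over the sorted
probabilities, comparing mean predicted probability with the empirical
positive fraction; the expected calibration error is the count-weighted
mean absolute gap. Ten bins by default (the full-scale bin count is not
stated); per-plot design weights are supported because the validation
sample is stratified, with the unweighted form as default since the
full-scale analysis does not state that weighting was used.

## Accuracy assessment

Validation plots are 100×100 m; a plot is called natural when *strictly*
more than half of its hundred 10 m pixels exceed the threshold (pixel
rule `p ≥ t`, closed on the left, so threshold 0 classifies everything
positive). Estimates follow the general estimators for stratified random
sampling: overall accuracy is the stratified mean of the agreement
indicator,

$$\widehat{OA} = \frac{\sum_h N_h \bar y_h}{\sum_h N_h},\qquad
\hat V(\widehat{OA}) = \frac{1}{N^2}\sum_h N_h^2\Big(1-\frac{n_h}{N_h}\Big)\frac{s^2_{y,h}}{n_h},$$

and user's/producer's accuracy are combined ratio estimators
$\hat R = \hat Y/\hat X$ with Taylor-linearized variance
$\hat V(\hat R) = \hat X^{-2}\sum_h N_h^2 (1-n_h/N_h)
(s^2_{y,h} + \hat R^2 s^2_{x,h} - 2\hat R s_{xy,h})/n_h$, where for UA
$x_u$ indicates a positive prediction and for PA a positive reference.
Confidence intervals are ±1.96 SE, clipped to [0, 1]. The
finite-population correction is retained — it vanishes when
$N_h \gg n_h$, the realistic case; single-plot strata contribute their
mean with a zero variance term and a warning; a ratio with $\hat X = 0$
is reported as not available rather than an error. In the census limit
the estimators reduce to raw confusion-matrix rates with exactly zero
standard errors, and under a self-weighting design to plain proportions —
both exact identities in the tests, alongside a Monte-Carlo check of the
design variance via hypergeometric resampling.

`threshold_sweep()` re-evaluates the estimator across a grid, reporting
the OA-optimal threshold (ties to the smallest grid point), the balanced
threshold minimizing |UA − PA|, and the band of thresholds with OA within
1 percentage point of the maximum. At threshold 0, UA equals the
stratified prevalence of reference positives — an exact identity used as
a test. `error_rates_at_extremes()` summarizes high-confidence failures
with raw, unweighted counts (the published counts are raw; a weighted
variant can be built from the estimator directly).

## Numerical and interface choices

* All generators and fits are pure functions of their seed and
  configuration; determinism is asserted bitwise where meaningful.
* Quantization uses R's native half-to-even rounding.
* The stitcher treats a pixel with no covering window as nodata rather
  than an error.
* No GDAL binding is required anywhere: rasters are plain matrices with
  an affine descriptor, and tile I/O uses 8-bit TIFF plus JSON sidecars.
  Cloud-optimized layouts, reprojection and the full-scale UTM tiling
  scheme are out of scope.
* The command-line front end (`inst/cli/nfmap`) is a thin dispatcher over
  the exported functions for evaluation, sweeps and calibration on CSV
  and tile files; the R API is the primary interface.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at the
desk preset (30 scenes of 32², 3 members, 50 epochs — minutes on one
core), the estimator Monte-Carlo at a 10⁴-unit population with 10⁵
hypergeometric replicates, and calibration recovery at 10⁵ draws. These
sizes are the package's fixed study conditions; the full-scale values
(128² scenes, 5 members, batch 512, 1.2 M locations) remain the
documented defaults of the corresponding configuration objects.

## Known limitations

The toy regime demonstrates correctness, not remote-sensing skill:
synthetic classes are far cleaner than real landscapes, where boreal
plantations with century rotations, shaded agroforestry, and sparse
savanna sit at or beyond the decision boundary. The desk model is far
below full capacity, and the generator's independent per-pixel source
noise understates the spatially correlated errors of real label sources.
Area estimation (as opposed to accuracy estimation) and re-labeling of
plots from imagery are out of scope.
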