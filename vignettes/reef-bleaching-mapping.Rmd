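---
title: "Methods: hyperspectral coral-bleaching mapping on synthetic reef scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral coral-bleaching mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefbleach)
```

## Scope and workflow

`reefbleach` implements the analysis chain between a georeferenced VNIR
radiance datacube of a shallow reef plus an in-water survey table and a
thematic accuracy report: reflectance conversion against a white
reference, blue/green log-ratio bathymetry with survey calibration,
water-column correction, per-(genus, bleaching-level) signature
extraction, normalized-difference bleaching indices, RBF-kernel SVM
classification with unsupervised refinement flags and spume exclusion, and
an excessive-area-aware accuracy assessment. Because no public scene with
per-pixel coral truth exists for this design, the package's first-class
component is a scene simulator: every downstream stage is exercised
against synthetic cubes whose bottom type, depth, and noise are known
exactly.

Platform concerns — flight operations, gimbal stabilization, push-broom
orthorectification, photogrammetric DEMs — are out of scope; simulated
scenes are generated already georeferenced.

## The synthetic scene generator

The generator's job is to emulate the features the analysis chain must be
sensitive to, with known truth, not to be a radiative-transfer code.

**Endmembers.** Coral spectra are convex mixtures
`w · bleached + (1 − w) · pigmented`, with `w = (6 − level)/5`, of two
smooth anchored shapes: a bright bleached-skeleton shape (mean ≈ 0.65)
with local elevation near 400 nm and 750 nm, and a genus-specific
pigmented shape (mean ≈ 0.19) with the strong blue-to-green rise of
healthy coral (R540/R480 ≈ 2.1) and a modest NIR red edge. Mixing makes
band-mean brightness strictly decreasing from level 1 (severely bleached)
to level 6 (healthy), and bleached levels elevated near 400/750 nm
relative to unbleached — the two qualitative contracts the field supports.
A seeded smooth ±5% multiplicative wiggle differentiates genera. The
background classes are sand (bright, gently rising), benthos (sand dimmed
by a spectrally flat 0.40 — a pure albedo contrast), optically deep water
(dark), and spume (flat 0.90; bright foam whose exact value is
immaterial). No claim is made that these match any measured coral library;
only the ordering/shape contracts above are guaranteed, and tests rely
only on those.

**Water.** Two-way Beer–Lambert attenuation with a water-leaving offset:

`R_obs(λ) = R_bottom(λ) · exp(−2 k(λ) z) + offset(λ)`

The attenuation curve `k(λ)` is anchored at 0.10 m⁻¹ (480 nm) and
0.20 m⁻¹ (540 nm) — moderately clear coastal reef water, and the
`k_green > k_blue` ordering the ratio bathymetry requires — rising through
the red and steeply in the NIR (≈2.9 m⁻¹ at 750 nm to ≈30 m⁻¹ near
1000 nm, the published magnitude of water absorption there). The steep NIR
branch matters: it extinguishes bottom signal beyond ~750 nm within the
first metre, as real shallow-water spectra show; an early draft with NIR
attenuation an order of magnitude too weak left spurious NIR signal at
depth that distorted the depth-correction experiments. The water-leaving
offset is small (≤0.004) as appropriate for clear water. Sensor noise is
i.i.d. zero-mean Gaussian per band and pixel in reflectance units — the
simplest model that exercises the spectral/spatial filters; real
push-broom noise is spectrally and spatially correlated, which the
generator deliberately does not emulate.

**Scenes and surveys.** One irregular contiguous blob per class over a
sand background; depth is a smooth ramp rescaled to span exactly
`[0, max_depth]`. Survey tables sample coral pixels with correct genus,
level, depth, and coordinates derived from the affine geotransform;
sampling is lightly stratified (≥2 points per present coral class when the
budget allows) because an in-water survey records every class it
encounters, and a supervised experiment is ill-posed for an unlabelled
class. The default survey size is 64 points, the scale of a single-site
field campaign. Spume polygons relabel covered pixels; in the packaged
experiments survey records under foam are dropped, reflecting that divers
obtain no usable reference photos beneath surface foam — if contaminated
points are instead kept in training, a kernel classifier simply learns
"foam spectrum = that class" and the contamination becomes invisible to
recall-based assessment.

**What passing tests do and do not show.** The simulator has pure
per-pixel spectra (no sub-pixel mixing), no glint, tides, BRDF,
orthorectification artifacts, or correlated noise. Tests therefore
demonstrate the internal correctness and the qualitative behaviour of each
stage under controlled conditions — not field-accuracy claims.

## Bathymetry and water-column correction

The relative depth index is `ln(n R_blue) / ln(n R_green)` at the grid
bands nearest 480 and 540 nm (defaults; the method names colours, so the
reference wavelengths are explicit, configurable parameters). The natural
logarithm is used; any other base rescales the index and is absorbed by
calibration. The stretch `n = 1000` keeps both logarithm arguments above 1
for reflectances above 0.1%; pixels at or below that are flagged invalid
rather than propagated as NaN. Calibration is an ordinary least-squares
line from index to surveyed depth, clamped at 0 m.

The index's albedo tolerance is real but partial: a spectrally flat
brightness change (bright sand vs dark benthos) moves the index far less
than a 1 m depth change, which the tests verify; a bottom type with a
different blue:green *shape* (pigmented coral, ratio ≈ 2 vs sand ≈ 1.2)
shifts the index like a depth offset. The packaged bathymetry experiments
therefore run on uniform-albedo bottoms, and `analysis/03_depth.R` shows
honestly degraded agreement on a mixed coral scene. Deeper than about
6–8 m the band-ratio approach loses reliability; `run_pipeline()` warns
when an entire calibrated scene is beyond its configurable `depth_limit`
(8 m).

The water-column variance share is the fitted quadratic
`y(x) = −18.353 x² + 10.805 x + 0.238` (percent, floored at 0) in the
log-transformed green/blue ratio `x = ln(R_green/R_blue)`, and the
correction rescales each spectrum by `1/(1 − y/100)`. Two properties of
this published fit are worth stating plainly. First, its analytic maximum
is `y ≈ 1.83%` at `x ≈ 0.294`, so the correction is intrinsically gentle —
a ≤1.9% rescale. Second, it responds only inside the quadratic's positive
window `x ∈ (−0.02, 0.61)`: for heavily bleached (near-white) bottoms the
green/blue ratio sits near 1 and `y` floors to 0. Consequently the
depth-effect experiments — same pigmented class at 1 m vs 2.3 m, where the
correction should and does narrow the spectral divergence — are run on an
unbleached coral class on the full sensor grid; with endmember
perturbations that push `x` off the responsive window the improvement can
shrink to nothing. This fragility is a property of the correction model,
not of its implementation, and is why the correction is exposed as a
stage rather than silently trusted.

## Signatures, indices, numerical conventions

Signature extraction averages all in-window pixels (default 3×3, to absorb
georeferencing jitter) of all records in a (genus, level) group; training
spectra for classification use the 1×1 window instead, because border
records' 3×3 windows can leak background pixels into the labels. The
signature-accuracy score is deliberately pluggable, since the field's
reports print it without defining it: the default is the percentage of
bands agreeing within 10% of the larger of the two spectral ranges
(symmetric by construction; a degenerate flat pair falls back to exact
equality).

The index registry is shipped as data (`inst/extdata/bleaching_indices.csv`)
— 34 normalized differences plus the genus ratio — so the whole table is
encoded once and cross-checked by a fixture test. The printed source of
the genus ratio is parenthesised ambiguously; it is evaluated as
`(R_540 − R_575)/(R_450 + R_586)` by analogy with every other entry.
Index wavelengths snap to the nearest grid band (no interpolation: at a
2.2 nm grid the gain would be negligible), with an error if the nearest
centre is more than one band-spacing away. One index references 395 nm
while the 274-band sensor grid starts at 400 nm, so `evaluate_table1()`
has a `strict` switch: the default errors on uncovered wavelengths; the
pipeline runs `strict = FALSE` and skips them with a warning. NDVI
variants use NIR 750 nm against green 550 nm or yellow 600 nm — named
colours made concrete as defaults.

Other conventions: pixels are 0-based `(row, col)` with centres at integer
coordinates; `geo_to_pixel` rounds half toward negative infinity so the
pixel/geo pair is exactly inverse on integer pixels; reflectance is
clipped to [0, 1] at every stage that can leave it (glint and corrected
values included); ENVI persistence is little-endian float32 BIL/BSQ with
unknown header keys preserved verbatim.

## Classification and denoising

The classifier is a maximum-margin SVM with the radial-basis kernel
`exp(−γ‖x_i − x_j‖²), γ > 0`, one-vs-one multiclass, from the libsvm
implementation behind `e1071`; the package's own `rbf_kernel()` states the
kernel explicitly and is property-tested (symmetry, PSD Gram matrices).
Hyperparameters are unstated in the field reports this design follows, so
the defaults are the standard scalings `γ = 1/(n_bands · mean band
variance)` and `C = 10`, both exposed. The optional image-gamma
brightening (`≤75%`, `v^(1/(1+g))`, default off) is a different "gamma"
from the kernel parameter — the two are deliberately named apart.
Unsupervised k-means partitions only *flag* pixels whose supervised label
disagrees with their cluster's majority; they never overwrite labels.
Denoising is Savitzky–Golay polynomial smoothing along bands (order 2,
window 5 by default; implemented as a banded smoother matrix checked
against the reference filter) followed by a per-band 3×3 spatial median
with border replication (an exact vectorized median, not a histogram
approximation). Windows of 1 are identities.

## Accuracy assessment

One report row per (genus, level) in the survey: a point counts as found
when the class map contains its class within a 3×3 window of its pixel
(point-to-map matching needs a tolerance; one pixel of jitter is the
natural choice). Point accuracy `100·found/total` is reported truncated to
3 decimals — the convention the reference ratios follow (3/14 → 21.428).
The excessive-area flag fires when a class's mapped share of the scene
strictly exceeds `factor ×` its reference prevalence; the factor defaults
to 5, prevalence comes from scene truth in synthetic work or from the
analyst, and an absent prevalence vector disables EA assessment rather
than flagging everything. The overall accuracy is 0 for EA rows and
otherwise `min(signature accuracy, points accuracy)` — a combination rule
*inferred* from exact agreement with all twenty rows of the reference
assessment tables, and encoded as such in a fixture test. One printed
reference cell (2/3 → "66.667") rounds where every other fractional cell
truncates; the package follows the truncation convention and the fixture
test documents the single discrepant cell.

## Experiment sizes

The packaged experiments are sized to run in seconds to a few minutes on
one core while keeping the study conditions meaningful: the
parameter-recovery experiment uses a 128×128 scene on the full 274-band
grid, six coral classes, noise sd 0.01, depths ≤ 3 m, a 64-point survey,
and requires ≥0.90 per-class recall; bathymetry properties use 64×64
zero-noise scenes; unit tests use smaller grids (40–120 bands) where the
spectral resolution is not the point.

## Known limitations

* Endmembers are synthetic; only ordering/shape contracts are guaranteed.
* The depth index degrades on mixed bottoms whose blue:green shapes
  differ; calibration absorbs offsets only per bottom type.
* The water-column correction is capped at a 1.86% rescale by the fitted
  quadratic and is ineffective for near-white bottoms.
* Hard per-pixel classification only: no sub-pixel mixture analysis.
* Local planar georeferencing; no datum or projection handling.
* Accuracy reports measure detection and mapped-area plausibility, not
  producer/user accuracy matrices or kappa.
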