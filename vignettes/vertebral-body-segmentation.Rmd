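---
title: "Vertebral body segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebral body segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vbseg segments vertebral bodies on 2D sagittal spine slices in four
stages: initial filtration, cascade-classifier detection, patch-based
Active Appearance Model (AAM) landmark localization, and closed
centripetal Catmull--Rom contour interpolation. This vignette explains
each model, its assumptions and tunable parameters, the synthetic
phantom that stands in for patient data, and the design decisions taken
where the procedure admitted more than one reasonable reading.

All coordinates in the package are global pixel coordinates: `x` is the
column index, `y` the row index, both 0-based, with pixel centers at
integer positions. Masks are pixel sets on the same grid.

## Initial filtration

Sagittal spine MR slices suffer from low resolution, a smooth
multiplicative intensity inhomogeneity (IIH) caused by coil
sensitivity, and noise. The filtration chain addresses the three in
order.

**Upsampling.** `upsample()` uses separable cubic convolution with the
Keys kernel. The kernel parameter `a` is exposed
(`preprocess.kernel_a`, default `-0.5`); the default is the
Catmull--Rom member, which has linear precision (ramps are reproduced
exactly) and a sharp high-frequency response. The default factor is 2
(`preprocess.upsample_factor`); output intensities are clipped to the
input range so overshoot near edges cannot create negative values.

**IIH model.** The bias is modeled as a single global multiplicative
exponential in *depth from the skin*: observed = true × exp(−λ·d),
with d in millimetres measured inward from the fat–skin boundary. The
boundary itself is found per image row as the first column (from the
configured side, default left) whose intensity strictly exceeds a row
quantile (default 0.90), then smoothed with an 11-row running median.
This exploits the bright subcutaneous fat band that borders the skin
on sagittal lumbar slices. λ and the reference intensity I₀ are
estimated by a least-squares line through log-intensity versus depth
over foreground pixels (above the global Otsu threshold). Pixels
shallower than 5 mm are excluded from the fit: they belong to the fat
band, a different tissue class whose higher baseline would otherwise
bias the slope. `correct_iih()` divides by the bias and rescales so
the image mean is preserved exactly; the tests assert that refitting
after correction shrinks λ by more than an order of magnitude.

The verbal description of this correction admits several concrete
formulas; the log-linear least-squares reading was chosen because it
is closed-form, stable on small foregrounds, and directly testable —
the tests require the generator's λ back within 15% at the default
phantom settings.

**Selective Gaussian denoising.** IIH correction amplifies deep-pixel
noise by exp(λ·d). `selective_gaussian()` therefore averages each
pixel with the Gaussian-weighted neighbours whose intensity difference
stays below `edge_threshold · exp(λ·d)` — the same exponential
parameterizes the intensity window, so the tolerance follows the noise
amplification. Pixels with no qualifying neighbour are untouched,
which makes the filter idempotent on piecewise-constant images with
over-threshold steps and exactly edge-preserving on ideal steps.

## Vertebra detection

Detection is a Viola–Jones style cascade: integral images, an extended
set of Haar-like features evaluated with variance normalization (so
affine intensity changes do not move responses), discrete AdaBoost
over decision stumps, and an attentional cascade.

Feature kinds: horizontal/vertical two-rectangle edges, three-rectangle
lines, a center–surround, and — behind the `tilted` flag, off by
default — a diagonally offset rectangle pair that responds to
45-degree structure while remaining computable from the ordinary
integral image. Positions and sizes are enumerated on a stride grid
(`feature_stride`, default 3 px) to bound the pool.

Defaults follow the classical detector: 24×24 window, up to 12 stages,
per-stage hit-rate target 0.995 and false-alarm ceiling 0.5, stage
thresholds lowered until the hit-rate target is met on the training
split. Stage *k* trains against negatives still accepted by stages
1..k−1, mined by seeded random window sampling from the negative
images. Two kinds of negative sources are supported: vertebra-free
reconstructions (the ground-truth boxes inpainted away) and annotated
originals whose mined windows must keep IoU < 0.2 with every true box.
The second kind supplies the *hard* negatives — windows straddling
discs or the fat band — without which a cascade trained only on
reconstruction negatives never sees vertebra-adjacent context and
generalizes poorly to sliding-window scanning. Training stops early
with a warning when
no false positives remain minable; on the high-contrast phantoms this
typically happens after two stages, which is expected behaviour, not a
failure.

At detection time an image pyramid (factor 1.1) is scanned with a 2-px
step; windows with zero intensity variance are rejected outright; raw
hits are grouped by connected components of the IoU ≥ 0.3 graph,
groups smaller than `min_neighbors` (default 3) are dropped, and each
surviving group reports its mean box with the raw-hit count as score.
A final size filter keeps boxes within [0.5, 2] × the median area —
the band constants are a package choice, as is the median reference.

## Training-data synthesis

Positive augmentation warps annotated crops with thin-plate splines:
per-landmark Gaussian control displacements (default 2% of the crop
width) plus global rotation (±8°) and scale (±10%) jitter. The TPS
solves the standard kernel system with U(r) = r²·log r; the image is
resampled by backward mapping through the inverse warp (fitted on the
swapped control points — an approximation that is exact for affine
warps), landmarks are mapped forward.

Negative reconstruction removes each vertebra (box dilated by 10%) by
harmonic inpainting: the masked region solves the discrete Laplace
equation with Dirichlet data from the unmasked neighbours, by SOR with
the classical optimal relaxation factor for the hole's effective grid
size. Diffusion inpainting is a deliberate stand-in for exemplar-based
methods: it is fully testable against an exact sparse solve and obeys
the discrete maximum principle, and the filled texture only has to
stop a detector from firing, not to look plausible to a radiologist.

## Patch-based AAM

**Shape model.** The 16-point outlines are aligned by generalized
Procrustes (translate to zero centroid, scale to unit norm, rotate by
least squares, iterate to a fixed point), then PCA on the aligned
vectors keeps the smallest number of modes reaching 95% variance. The
model stores the mean shape, modes, eigenvalues and the mean training
centroid size (needed to re-instantiate pixel-scale shapes).

**Appearance model.** At each pyramid scale (defaults 0.5 and 1.0),
17×17 patches are sampled at the landmarks with bilinear subpixel
interpolation (edge replication near borders), z-scored per patch for
photometric invariance, concatenated into one vector, and reduced by
PCA to 90% variance. Patch shape and variance fractions are exposed in
the configuration; none of them is prescribed by the procedure being
modeled, so they are package defaults, logged with the model.

**Fitting.** The shape is parameterized by a global similarity (4
parameters) plus the shape-mode coefficients, clamped to ±3 standard
deviations. Patches translate rigidly with their landmark (they do not
rotate with the pose — the usual patch-AAM simplification), so the
motion Jacobian is constant and the template-gradient steepest-descent
images can be precomputed per scale. The inverse-compositional
variants share this structure and differ in how appearance is handled:

* **POIC** projects the appearance basis out of the residual and the
  Jacobian; everything is precomputed, making it the fastest and the
  least accurate under appearance variation.
* **AIC** alternates: shape step against the residual of the previous
  appearance estimate, then re-solve appearance.
* **MAIC** applies the appearance update *before* recomputing the
  residual used by the shape step. The "modification" is not specified
  beyond its name in the literature the package follows; this ordering
  is the package's documented interpretation.
* **SIC** solves shape and appearance increments jointly, with the
  Jacobian rebuilt from the current reconstruction each iteration.
* **WIC** eliminates the appearance parameters in closed form each
  iteration (they are optimal given the shape) and takes the shape
  step on the projected residual with the reconstruction-gradient
  Jacobian — SIC accuracy at nearly POIC cost.

Parameter updates are applied additively; a 0.5 damping (up to four
halvings) guards iterations whose cost increases, and degenerate
Hessians fall back to an eigenvalue pseudo-inverse with cutoff 1e-10.
The iteration budget (default 25) is split evenly across pyramid
scales with the remainder at the finest scale; iteration 0 is the
initialization, and every intermediate shape is recorded at full-image
scale so convergence tables can be built per iteration. Whether the
original procedure fitted at several pyramid scales is unstated; the
two-scale default is the package's choice and a single-scale model is
one configuration away.

Initializations: evaluation mode perturbs the ground-truth shape by a
seeded similarity (Gaussian translation with sd 5% of the bounding-box
diagonal per axis, 3° rotation sd, 2% scale sd); deployment mode
scales the mean shape into the detected box at 80% fill. The
perturbed-ground-truth device mirrors how such pipelines are
benchmarked; the box-aligned mean shape is what runs on unannotated
images.

## Contours and areas

The 16 fitted landmarks are interpolated with a closed Catmull--Rom
spline in the centripetal parameterization (knot increments equal the
square root of chord length, `alpha = 0.5`, configurable), evaluated
by the Barry–Goldman pyramid with cyclic end conditions and 20 samples
per segment. Centripetal knots guarantee no cusps or local
self-intersections for simple control polygons; `self_intersects()`
verifies the property explicitly. Rasterization uses the even–odd rule
at pixel centers; areas come either from the shoelace formula on the
dense polyline or from mask pixel counts — the two agree within 2% on
phantom vertebrae, and doubling the polyline density moves the area by
less than 0.1%.

## Evaluation machinery

For an automatic mask S and a reference mask T (areas in pixels):
TPF = 100·|S∩T|/|T|, FNF = 100·|T∖S|/|T|, FF = 100·(1 −
(|S∖T|+|T∖S|)/|T|). TPF + FNF = 100 is an exact integer identity;
FF ≤ TPF always, FF = 100 iff the masks coincide, and FF is reported
unclamped (it can go negative under gross over-segmentation).

Summaries follow the mean ± halfwidth convention with halfwidth =
1.96·σ/√n (σ the n−1 standard deviation) — the normal-approximation
95% interval. This convention was adopted because it exactly
reproduces the published ± columns from their printed σ and n (σ 3.64,
n 50 → ±1.01; σ 7.02, n 100 → ±1.38).

The ICC uses the two-way mean squares over subjects × raters. The
reported default is the *consistency* model — the wording "consistency
of the areas" points there — with absolute *agreement* selectable
(`model = "agreement"`); single and average measures are both
returned, with F-based confidence bounds. Whether the original
analysis used consistency or agreement, per slice or per vertebra, is
not derivable from the text; the choice is flagged here and in the
function documentation.

Cross-validation splits *by image* (never by vertebra), trains the AAM
on the complement, fits the held-out vertebrae from seeded perturbed
initializations, and scores against the rasterized ground-truth
contour; per-fold statistics are summarized as above and the mean row
is the arithmetic mean of fold statistics.

## The synthetic phantom

No study data is distributed, so `generate_phantom()` emulates what
the pipeline needs from a sagittal lumbar T1-like slice: a 256×256
grid at 0.7 mm/px; five bright vertebral bodies (~34×26 px, matching
the relative body size on a 384-px lumbar slice) stacked along a
gently curved column; darker discs between bodies and a darker canal
band behind them; dark air and a bright subcutaneous fat band at the
left border; a multiplicative exp(−λ·d) bias (λ = 0.006/mm, strong
enough that correction is measurable but the deep column remains above
noise); Gaussian noise (σ = 6 on a 0–240 intensity scale, ~3% of body
contrast). Body outlines are TPS-perturbed instances of a fixed
16-point template — 4 rounded corners plus 3 points per edge, ordered
clockwise from the anterior-superior corner; the anatomical identity
of the original 16 expert points is unstated, so this template is the
package's documented convention, used consistently by the shape model
and the contour stage. Ground truth per vertebra is the landmark set,
its bounding box, and the rasterized contour mask.

What the phantom does *not* emulate: spin-echo contrast physics,
partial-volume fade at body boundaries, pathology (compressed discs,
herniation), and inter-expert annotation variability. Tests passing on
phantoms therefore demonstrate the machinery — estimators recover
known generator parameters, fitters converge, identities hold — not
clinical-grade accuracy; phantom overlap scores sit well above what
heterogeneous patient data yields, exactly because the phantom
boundary model and the segmentation model agree.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale sizes
chosen as a deliberate miniature of the full protocol: 50 training
phantoms (250 vertebrae) for the detector, 40 vertebrae for the AAM,
10 held-out phantoms for detection statistics, two 25-iteration
passes over 10 vertebrae for algorithm comparison, and 5-fold
cross-validation over 100 phantoms (500 fits). Determinism is strict
throughout: every stochastic step (phantom synthesis, negative mining,
perturbations, fold splits) flows from explicit integer seeds, and
model files serialize numeric blocks as base64 doubles so a save/load
round trip reproduces fits bit-for-bit.

Known limitations: the IIH model is 1-D in depth and cannot represent
lateral bias; diffusion inpainting blurs texture; the detector reports
square boxes even though vertebral bodies are slightly wider than
tall; MAIC follows the package's reading of an under-specified
variant; and the agreement-model ICC confidence bounds reuse the
consistency F interval (adequate for paired raters, approximate
beyond).
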