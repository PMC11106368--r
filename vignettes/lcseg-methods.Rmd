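---
title: "Geometry-based locus coeruleus region estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-based locus coeruleus region estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The locus coeruleus (LC) is a thin, elongated noradrenergic nucleus in the
rostral pons, on the order of 14.5 mm long and a couple of millimetres
wide. On conventional T1-weighted MRI it has *no* contrast against the
surrounding pontine tissue, so its position can only be approximated from
neuroanatomical geometry: roughly 3 mm lateral of the midline, about 1 mm
rostral of the floor of the fourth ventricle, and 16–20 mm above the
pontomedullary junction (PMJ). `lcseg` implements that geometric protocol
as code, plus the machinery needed to train, compare and evaluate
automatic localizers of the resulting *presumptive LC region* — a
deliberately inflated region (about 19.7 mm³ per side) that contains the
LC (about 7 mm³ per side in externally delineated labels) and prioritizes
sensitivity over specificity.

A consequence of deliberate inflation is a hard ceiling on the achievable
Dice overlap against a tight LC label: if the region is `alpha` times the
label's volume and contains it, Dice cannot exceed `2 / (1 + alpha)`
(`diceCap()`). At the observed volume ratio of 2.7 the cap is 0.54 — an
essential reference point when reading evaluation scores of inflated
masks against specific labels.

## The synthetic brainstem phantom

Real training data for this problem are brain-extracted T1w volumes with
manually drawn region masks. The package's stand-in is a seeded phantom
(`makePhantom()`, `makeCohort()`) emulating the geometry that the manual
protocol relies on:

* a brainstem-like column of "pons" tissue (distinct medulla / pons /
  midbrain radii, softened transitions) in a zero background, at
  (0.7 mm)³ voxels on a 44 × 44 × 96 grid (~31 × 31 × 67 mm);
* a CSF-filled fourth-ventricle wedge on the posterior surface of the
  pons, whose floor reference is the `ventricleRef` landmark;
* a bilateral ground-truth LC: tapered spindles, nominally 14.5 mm long,
  placed by the landmark rule (1 mm rostral of the ventricle reference,
  ±3 mm lateral of the midline plane; the height above the PMJ falls in
  the 16–20 mm band by construction);
* an enlarged presumptive mask per side: the same spindle inflated by a
  radial margin;
* Gaussian noise (sigma 0.05 against a tissue contrast of 1), a smooth
  multiplicative bias field (±10%), and *no intensity difference between
  LC and pons* — the defining property of the task.

Two calibrations tie the phantom to the published volume scales. The
spindle's radius scale is solved by bisection so that the *voxelized*
truth volume matches ~7 mm³ per side, and the mask margin so that the
voxelized mask matches ~19.7 mm³ per side (each jittered ±10% per case).
Solving for voxelized rather than analytic volume makes the targets exact
under discretization at 0.7 mm. A consequence worth stating: at ~7 mm³
over 14.5 mm length the mean cross-section is ~0.5 mm radius, so the
voxelized spindle is a one-to-few-voxel-wide column whose maximal
diameter (~1.2 mm) sits below the 2–2.5 mm literature envelope for LC
width; we prioritize the printed volume scale, which the Dice-cap
arithmetic depends on, over the width quote.

Landmark positions are jittered by ±1 mm per case (independent per
landmark), the two sides by an extra ±1/3 mm, and shape scales by ±10%.
One deliberate design rule emerged during implementation: **each landmark
constrains its own axis**. The lateral coordinate comes from the midline
plane, the depth and rostro-caudal coordinates from the ventricle
reference. If, instead, the LC position inherits the ventricle
landmark's *lateral* jitter, that jitter has no image correlate at all —
no image-driven method can recover it even in principle, and every
localizer fails by construction rather than by merit. The same
decomposition is used by `geometricLCMask()`, so the codified protocol
and the phantom are consistent.

The `site` knob emulates an acquisition change (3T-vs-7T flavour): site B
applies a monotone gamma remap with a gain (`I -> 1.5 * I^0.8`) and 1.5×
noise, leaving geometry untouched. The gain term matters: the phantom's
dominant tissue intensity is 1.0, which a pure gamma maps to itself, so
without a gain the "domain shift" would barely shift anything that
intensity normalization could fix.

What the phantom does **not** emulate: real anatomical shape variability,
partial-volume effects beyond linear resampling, MR physics (sequence
contrast, distortions), or inter-rater labelling noise. Passing tests on
phantoms therefore demonstrates that the *machinery* behaves as specified
under controlled geometry, not that any score generalizes to real MRI.

## The geometric mask

`geometricLCMask()` is the protocol as an algorithm: place the centre
3 mm lateral of the midline on the requested side and 1 mm rostral of
the ventricle-floor reference (along the PMJ normal by default —
"rostral" — with the ventral-normal reading available via
`rostralAxis = "ventral"`), clamp the height into the 16–20 mm PMJ band,
and voxelize an axis-aligned tapered spindle (default length 15 mm)
whose radius scale is bisected so the voxel-count volume matches the
19.7 mm³ target within a voxel. A voxel belongs to the mask when its
centre lies inside the analytic shape; the largest 26-connected
component is kept. The spec's alternative of a 4 mm-long mask (the band
height) was rejected during implementation: a 4 mm mask cannot overlap a
~15 mm enlarged region at Dice ≥ 0.5, and a 19.7 mm³ target spread over
4 mm voxelizes poorly at 0.7 mm.

## The phase image

`phaseImage()` computes `Re F^{-1}[F / (|F| + eps * ||F||)]` with
`eps = 0.001` and `||F||` the spectral L2 norm (the L∞ option is
exposed). It discards Fourier magnitude — hence the intensity
distribution — while keeping edge structure, and is *exactly* invariant
to global positive intensity rescaling, which is why it is the preferred
input representation under acquisition shift. The whole-volume 3D DFT is
used (not per-slice). The transform preserves Hermitian symmetry, so the
imaginary residual of the inverse transform is at round-off level; the
real part is returned. `normalizeStd()` divides by the standard
deviation of the nonzero (foreground) voxels, matching brain-extracted
inputs whose background is exactly zero.

## The ELV-style localizer

`elvMap()` is a label-fusion localizer without deformable registration:
for every atlas and every integer-voxel translation within ±5 mm, a
*transformation validity* weight is computed and the atlas's presumptive
mask is accumulated under that translation with that weight; atlases are
then averaged. Design choices the package makes (each exposed in
`elvConfig()`):

* validity = softmax of windowed normalized cross-correlation between
  the (phase-transformed) atlas and test images, with softmax width
  0.005;
* similarity images are pre-smoothed with a 0.8-voxel Gaussian *for
  scoring only*. The phase transform whitens the spectrum, so on a
  piecewise-constant phantom the unsmoothed NCC is dominated by noise;
  mild smoothing restores the alignment signal. Label accumulation is
  never smoothed;
* the scoring window is inset from the grid border by the translation
  radius, which makes the FFT-accelerated correlation *exactly* equal to
  direct sliding-window dot products (no wrap-around contamination); an
  additional world-space box can restrict scoring to the brainstem;
* per-atlas weights are normalized to sum to one, the fused map is
  clipped to [0, 1], binarized at 0.5, and reduced to its largest
  26-connected component.

The width and smoothing defaults were calibrated once on a six-case
phantom cross-validation and then frozen; they are the analogue of the
hand-tuned registration parameters that atlas pipelines require. The
optional intensity prior (`intensityPrior()`) multiplies the map by a
mode-rescaled Gaussian likelihood of the test intensities under the
pooled in-mask atlas intensities — the "phase + image" variant.

## The 3D U-Net

`unetTrain()` / `unetPredict()` implement a patch-based 3D U-Net with
two down-sampling stages, 3³ zero-padded "same" convolutions, 2³ max
pooling, nearest-neighbour upsampling with a reducing convolution and
skip concatenation, and a sigmoid head. Convolutions run through an
im2col + BLAS GEMM kernel with the exact adjoint for backpropagation
(finite-difference-checked); each convolution is followed by per-channel
instance normalization, which keeps activation scales fixed so that
training makes progress within a small step budget. Adam is the
optimizer; the learning rate starts at 0.002 and drops by 95% every five
epochs (`lrSchedule()`).

The training objective is the two-class generalized Dice loss
(inverse-squared-volume class weights) — the class-balanced Dice
formulation that standard Dice segmentation layers implement. The plain
Dice loss (`diceLoss()`, also exported and used for evaluation traces)
provably collapses here: the target occupies well under 0.2% of a patch,
and the cheapest descent direction is an all-background prediction from
which saturated sigmoids cannot recover. Patch sampling draws half the
patches around target voxels (with quarter-patch jitter so the target is
not always centred) and half uniformly. Inference pads the volume to the
patch size, scores overlapping patches at stride 10 and averages every
voxel over all windows covering it (`slidingWindowMap()`, whose coverage
counts are verified against brute-force window enumeration).

Reference hyperparameters (132³ patches, 16 filters, batch 8, 20 epochs,
learning rate 0.002 dropping 95% every 5 epochs) are the defaults of
`unetConfig()`. The experiments in the test suite use the desk-scale
configuration 24³ patches, 8 base filters, batch 2, 10 epochs of 15
gradient steps at a flat learning rate of 0.005 — sizes chosen so a
single CPU trains a cross-validation fold in about a minute. Three of
these deserve comment. The patch is reduced from the reference size
because a 132³-patch step is three orders of magnitude more compute
than a 24³ step, while the phantom's informative context (the ventricle
wedge and pons boundary near the LC) fits within 17 mm. The learning
rate is scaled up from 0.002, and the 95% drops are disabled within the
10-epoch run, because the step budget (~300 mini-batches) is roughly
two orders of magnitude below a GPU training run; with Adam, fewer
steps at a proportionally larger, undecayed rate is the standard
compensation, and the published decay schedule remains the package
default (`lrSchedule()`). Training patches mix target-centred draws
with two kinds of hard negatives — the contralateral mask (the decisive
lesson for distinguishing the trained side from its mirror image) and
the rostro-caudal flanks of the target (which sharpen the along-axis
extent). At inference, scores outside the head (where the
brain-extracted input is exactly zero) are clipped to zero: a
patch-normalized near-empty background patch amplifies numerical noise
into meaningless scores.

## The atlas baseline

`buildFuzzyAtlas()` averages aligned, intensity-normalized images and
binary masks into a template with fuzzy masks (identity alignment for
the pre-aligned phantom cohort; user-supplied deformation fields
otherwise — no template download is involved: the template grid is the
cohort's own). `demonsRegister()` is an asymmetric diffeomorphic-demons
registration: the classic intensity-difference force, Gaussian fluid
smoothing of the update (sigma 1 voxel), optional scaling-and-squaring
exponentiation (on by default), composition, and Gaussian elastic
smoothing of the field (sigma 1.5 voxels), over a 3-level
multi-resolution pyramid with 30 iterations per level — parameters
exposed because such pipelines are hand-tuned per dataset.
Non-convergence (an MSD increase over a level) sets a `converged = FALSE`
flag rather than raising, so evaluation harnesses can record failures
per case, and `applyAtlas()` carries the flag through to its output.

## Evaluation machinery

`diceScore()` (two empty masks → 1 with a warning; empty prediction → 0),
`sensitivityScore()`, `binarizeLCC()` (26-connectivity; size ties break
toward the smallest linear voxel index — deterministic), `combineSoft()`
(voxelwise product then binarize, the fusion rule for combining two
localizers), `runLOOCV()` (leave-one-out with failure flags, evaluating
against the held-out case's enlarged mask), and `cohortStats()` (paired
two-sided t between left/right volumes; Pearson correlation between
left/right Dice; degenerate inputs handled explicitly: zero-variance
differences give t = 0, p = 1, zero-variance correlations are flagged
`NA`).

`regionalMeans()` propagates a mask to each map's grid when needed
(linear soft warp, then binarize at 0.5 — the same rule used for native
to dMRI-grid propagation) and averages map values under the mask.
`correlationScan()` computes Pearson r and p per (imaging, external)
variable pair on complete cases, Bonferroni-corrects by multiplication
with the total pair count (capped at 1), and optionally adjusts for
intracranial volume by residualizing *both* variables on ICV and
referring the partial correlation to n − 3 degrees of freedom. Outlier
sensitivity is reported (max Cook's distance per pair) and flagged —
never auto-excluded — replacing interactive visual inspection with a
reproducible diagnostic. Complete-case analysis, no imputation.

## Numerical choices and degenerate inputs

* Volumes carry a 4 × 4 RAS affine with 0-based voxel indexing; voxel
  size must equal the affine column norms to 1e-6.
* Resampling covers the same world extent, fills out-of-field samples
  with 0 (zero-background convention), thresholds binary masks at 0.5
  after linear warping, and clips soft masks to [0, 1].
* Spindle voxelization is centre-inside; volume targets are met by
  bisection on a monotone scale parameter (60 iterations).
* All-zero images are rejected by the phase transform (undefined
  normalization); zero-variance images by `normalizeStd()`.
* FFT round-off in the ELV accumulation is clipped at [0, 1]; weights
  are computed in a max-shifted exponential for stability.
* Training determinism: seeded initialization and sampling, single-
  threaded deterministic kernels; two runs with one seed are bitwise
  identical.

## Problem sizes used by the test suite

Phantom grid 44 × 44 × 96 at (0.7 mm)³ throughout; 6-case cohorts for
cross-validation experiments, 4 + 4 cases for the cross-site transfer
experiment; U-Net at the desk-scale configuration above; demons at 2–3
levels with 5–30 iterations depending on the check. These are the
package's chosen experiment sizes for a single-CPU environment; the
methods themselves accept the reference-scale settings unchanged.

## Known limitations

* The phantom's geometric regularity makes localization easier than on
  real anatomy; its scores are sanity floors, not forecasts.
* The ELV instantiation follows a one-sentence published description of
  the original method; its validity measure and transform family are
  this package's own choices, so published cross-validation scores for
  the original are context, not targets.
* The U-Net's desk-scale step budget trades accuracy for tractability;
  its phantom scores underestimate what the reference configuration
  reaches on real data with GPU-scale training.
* Translation-only ELV cannot compensate anatomy-dependent nonrigid
  variation; that is what the demons baseline is for.
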