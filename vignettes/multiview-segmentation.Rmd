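---
title: "Coarse-to-fine multi-view segmentation of volumetric angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine multi-view segmentation of volumetric angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the approach

Contrast-enhanced computed tomography angiography (CTA) renders the blood
pool bright, and segmenting the aortic lumen from such volumes is the first
step of aortic morphology analysis, stent-graft sizing and hemodynamic
modelling. Fully 3D convolutional networks are data- and memory-hungry;
`mvseg` implements the pragmatic alternative of a cascade of 2D networks
that together recover 3D spatial coherence:

1. **Coarse localization.** The scan is intensity-windowed, down-sampled
   4x in-plane, and every axial slice is passed through a small 2D U-Net.
   The stacked per-slice probabilities are binarized with a threshold
   selected on the validation set, giving a rough lumen mask whose only job
   is to say *where* the vessel is.
2. **Cuboid ROI.** A fixed-size axis-aligned cuboid (480 x 144 x 144 voxels
   at full scale, z-y-x) is centred on the bounding box of the coarse mask
   and cropped from the 2x-down-sampled working scan. Fixed size keeps the
   three view networks' input shapes constant; cuboids that overrun the
   scan are zero-padded to size.
3. **Three single-view segmenters.** The ROI is decomposed into axial
   (fixed z), sagittal (fixed x) and coronal (fixed y) slice stacks and a
   separate U-Net of identical architecture is trained per view. Each
   view's 2D probability maps are restacked into a 3D probability volume.
4. **Stack smoothing.** Each view's probability volume is smoothed with a
   1D Gaussian along the axis in which its predictions are independent
   (z for axial, x for sagittal, y for coronal), injecting the across-slice
   coherence a 2D network cannot learn.
5. **Fusion.** Three rules are implemented: *majority voting* on the
   binarized view masks; *averaging*, `p = (p_ax + p_sag + p_cor) / 3`
   followed by a validated threshold; and the *combined* rule, which sets
   the fused probability to exactly 1 or 0 where the three binarized views
   agree and falls back to the average where they disagree. The fused map
   is binarized and pasted back onto the scan grid (background outside the
   cuboid).

Every binarization threshold in the pipeline — coarse, per-view, and
fusion — is selected by exhaustive search over a 0.05-step grid as the
value maximizing mean per-case 3D Dice on the validation split, ties broken
toward the smaller threshold.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| window level / width | 200 / 800 HU | linear map of [-200, 600] HU onto [0, 255], clamped; brackets contrast-enhanced lumen |
| target spacing | (0.62, 0.73, 0.73) mm | voxel-size normalization before everything else (z, y, x) |
| coarse / working factor | 4 / 2 | in-plane down-sampling for localization and segmentation stages |
| cuboid size | (480, 144, 144) voxels | ROI at working resolution; axial slices 144 x 144, sagittal/coronal 480 x 144 |
| U-Net depth / filters | 2 / 8 | encoder levels and first-level channels; width doubles per level |
| loss / optimizer | BCE / Adam, lr 1e-4 | per-pixel binary cross-entropy on the sigmoid head |
| batch size | 20 coarse, 10 view | slices per step, sampled uniformly from all training slices (empty-mask slices included) |
| early stopping | patience 15 | on validation loss, best-epoch weights restored |
| augmentation | rotations, shifts, zoom | per-stage ranges: +/-10 deg, +/-20/+/-22 px, zoom [0.85, 1.15] coarse; +/-7 deg, +/-22/+/-22 px finer axial; +/-22/+/-72 px finer sagittal/coronal; drawn uniformly per slice pair on the fly |
| smoothing sigma | 1 slice | stack-Gaussian standard deviation |
| threshold grid | 0.05 ... 0.95 step 0.05 | granularity consistent with validated thresholds like 0.4 / 0.45 |

All of these live in one nested configuration (`default_config()`), can be
overridden from YAML (`load_config()`, unknown keys rejected), and are
exercised by the CLI (`mvseg phantoms | train | predict | evaluate`).

## The network engine

No deep-learning framework is assumed: the package carries a compact CNN
engine of its own. Convolutions are im2col + BLAS GEMM with zero "same"
padding (C++ via Rcpp/Armadillo), pooling is 2 x 2 max with argmax
bookkeeping, and the decoder upsamples by nearest-neighbour followed by a
3 x 3 convolution rather than a transposed convolution — the same role and
parameter class, without checkerboard artifacts. Weights are He-normal,
deterministic given the seed; the whole training loop (on-the-fly
augmentation, Adam, early stopping) is reproducible bit-for-bit under a
fixed seed on a fixed BLAS. Backpropagation is verified against central
finite differences in the test suite; one caveat worth recording is that
with zero-initialized biases some ReLU pre-activations sit exactly at the
kink, where a subgradient and a central difference legitimately disagree —
the gradient test perturbs biases off zero for that reason.

## The phantom generator

Training and evaluation run on synthetic contrast-enhanced vascular
phantoms, so the full pipeline is testable with no data download. A phantom
is a bright tube swept along a cubic-spline centreline (sampled at 0.4-voxel
steps) inside a darker background:

* default grid 128 x 96 x 96 voxels at 1 mm spacing; lumen radius 7-11 mm,
  matching an adult aorta, with an optional focal aneurysmal bulge
  (radius multiplier 1.4-2.0, i.e. dilatations beyond 3 cm diameter);
* branch tubes (2.5-4 mm radius, 10-18 mm long) attached to the main
  centreline;
* lumen intensities drawn per voxel from [250, 450] HU, background from
  [-50, 80] HU, Gaussian noise (sd 20 HU) on top — so the 200/800 window
  is exercised meaningfully rather than saturating;
* bright *distractor* blobs in the lumen intensity band, placed strictly
  disjoint from the lumen (at least ~2 mm from its surface, enforced via a
  distance transform). They emulate confounders such as prosthesis
  artifacts and neighbouring vessels; any false positive on them is
  attributable to the model, not to label noise.

What the phantoms do **not** emulate: CT physics (beam hardening, streak
artifacts, partial-volume blur), organ context, thrombus, or anatomical
tortuosity beyond smooth splines. A passing end-to-end check therefore
demonstrates that the cascade, the fusion arithmetic, the threshold
selection and the bookkeeping between grids are correct and that the
networks can learn a bright-tube appearance model — it does not certify
clinical-grade performance on real CTA.

## Desk-scale experiment

The self-contained experiment (also what `scripts/acceptance.R` runs) uses
a 16 train / 2 validation / 4 test split of phantoms, mirroring the
64/6/10 proportions of a full-scale study at a quarter of the case count.
Conditions, fixed a priori:

* phantoms at their default 128 x 96 x 96, 1 mm grid; the input grid is
  already isotropic so the spacing-normalization step is an identity here
  (it is exercised separately in unit tests);
* cuboid ROI 128 x 48 x 48 so that slice shapes stay divisible by
  `2^depth` (axial 48 x 48, sagittal/coronal 128 x 48);
* U-Nets of depth 2 with 8 base filters; 10 epochs of 40 Adam steps;
  batch 20 (coarse) / 10 (views); patience 15, which within a 10-epoch
  budget means no early abort, but the best-validation epoch is still the
  one restored;
* learning rate 1e-3 rather than the full-scale 1e-4: the reference value
  is tuned to a ~50k-slice corpus and tens of epochs, while a few hundred
  desk-scale steps need a proportionally larger step size;
* augmentation shift ranges scaled by the slice-size ratio between desk
  and full scale (e.g. +/-72 px on 480-px slices becomes +/-19 px on
  128-px slices); rotation and zoom ranges are resolution-free and kept.

With those conditions the fused segmentation reaches a mean test Dice
above 0.9 and exceeds the best single view, reproducing the qualitative
ordering that motivates multi-view fusion (the suite asserts the soft
bounds: fused >= 0.80 and fused >= best single view - 0.02).

## Numerical conventions and edge cases

* **Axis convention.** Arrays are `(z, y, x)`, 1-based as native in R;
  `data[k, , ]` is the k-th axial slice. File I/O (NIfTI via RNifti,
  MetaImage hand-parsed — a text header plus raw block) permutes from the
  on-disk x-fastest order; direction cosines beyond axis order are ignored
  with a warning for oblique inputs.
* **Windowing** maps `[level - width/2, level + width/2]` linearly to
  `[0, 255]` with clamping — the standard radiological semantics; network
  inputs are additionally divided by 255.
* **Resampling** is separable per-axis linear interpolation on voxel
  centres (`new_n = round(old_n * old_sp / new_sp)` preserves physical
  extent to within one voxel); labels always use nearest-neighbour and
  stay binary. In-plane down-sampling block-averages when the factor
  divides the grid (the usual case) and falls back to linear resampling
  otherwise.
* **Binarization** is `p >= t` everywhere, and threshold ties resolve to
  the smallest candidate, making selection deterministic.
* **Stack smoothing** renormalizes the truncated Gaussian kernel at volume
  borders, so constants are exactly preserved; `sigma = 0` is the
  identity.
* **Overlap metrics** define two empty masks as Dice/Jaccard 1, one empty
  mask as 0; surface distances are undefined (an error) for an empty mask.
  Surfaces are foreground voxels with a 6-connected background neighbour,
  the volume border counting as background; distances are voxel-centre to
  voxel-centre in physical mm via an exact anisotropic Euclidean distance
  transform (separable lower-envelope algorithm), cross-checked in the
  tests against an all-pairs brute force.
* **Coarse-to-working coordinates.** The cuboid centre is the bounding-box
  centre of the coarse mask (the natural derived point of a bounding-box
  localizer), mapped between grids on voxel centres with the in-plane
  scale `coarse_factor / working_factor`; the slice axis maps 1:1 because
  down-sampling is in-plane only.
* **Smoothing axis.** Each view is smoothed along its own stacking axis —
  the direction in which its 2D predictions are independent. Smoothing all
  three views along anatomical z would leave the axial view's main failure
  mode (in-plane confusions replicated across z) untouched; both options
  are available through `smooth_stack()`.
* **Paste-back** declares everything outside the cuboid background: the
  coarse stage's contract is precisely that the target lies inside the
  ROI, and a localization failure aborts loudly rather than silently
  producing an empty mask.

## Known limitations

* The engine is CPU-only and sized for desk-scale experiments; full-scale
  training (hundreds of 512 x 512 scans) would want a GPU backend behind
  the same module surface.
* Orientation handling is deliberately minimal (axis-aligned volumes);
  oblique acquisitions must be reformatted upstream.
* Single-class lumen segmentation only: no thrombus, no multi-label
  output, preoperative-style bright-lumen appearance assumed.
* The validated-threshold machinery assumes the validation split is
  representative; with only two desk-scale validation phantoms the
  selected thresholds are coarse (which the 0.05 grid acknowledges).
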