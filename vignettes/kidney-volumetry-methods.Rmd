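---
title: "Methods: automated parenchymal kidney volumetry in dual-station MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated parenchymal kidney volumetry in dual-station MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneyvol)
```

## The measurement problem

Neck-to-knee body MRI acquired for body-composition analysis covers the
kidneys across two overlapping axial imaging stations, each captured in a
separate breath-hold of roughly 224 x 174 x 44 voxels at
(2.232, 2.232, 4.5) mm, with a dual-echo reconstruction that separates a
water and a fat signal. **kidneyvol** measures *parenchymal* kidney volume —
cortex plus medulla, excluding the renal pelvis, calyces, major vessels and
cysts — from such data: a slice-wise neural network segments each station in
the water channel, the stations are fused onto one voxel grid, the two
largest connected components are taken as the left and right kidney, and
rule-based quality ratings flag subjects whose measurement should not be
trusted.

Because cohort imaging data are access-restricted, the package ships a
seeded phantom generator that emulates the acquisition geometry and the
failure modes the pipeline must handle. Every stage is exercisable — and
tested — end to end on phantoms alone.

## The phantom generator

`generate_subject()` builds a whole-trunk volume first and then cuts it into
two stations whose layout satisfies `2 * station_slices - overlap_slices =
z extent` (default 2 x 44 − 24 = 64; the overlap extent of the real
acquisition is protocol-dependent and configurable). Each kidney is a solid
superellipsoid (exponent 2.5, semi-axes drawn per subject from
anatomically plausible ranges of roughly 22–30 x 16–24 x 42–58 mm) with an
ellipsoidal medial concavity — the hilum — subtracted. The concavity is
rendered dark in the water channel and excluded from ground truth, exactly
the bright-parenchyma / dark-pelvis appearance an operator would segment.
Subtracting the concavity (or cysts) can strand tiny satellite fragments, so
each kidney's truth keeps only its largest connected body and the rest is
rendered dark; an anomaly-free truth therefore has exactly two components.
Default volumes land in the 90–160 cm³ per-kidney range reported for adult
populations, with an inter-kidney centre-of-mass distance near 115 mm.

Breath-hold misalignment is modelled by rigidly shifting the *source
content* of station 2 before extraction (default (1.5, 0, 2) mm, a
sub-voxel displacement typical of compliant subjects; intensities are
interpolated linearly, labels nearest-neighbour with consistent
`floor(x + 0.5)` rounding). Noise is additive Gaussian, drawn once on the
trunk volume and clipped at zero, so with zero motion the two stations agree
voxel-for-voxel on their shared slices — which makes the fusion ratings'
response to injected motion cleanly attributable to the motion itself.
Anomalies reproduce the failure cases the cohort contains: a missing kidney
(true volume 0), carved-out cysts, kidneys fused by a bright isthmus (one
truth component), and kidneys truncated at the outer station border.

What the phantom does *not* model: MRI physics (coil bias fields, Dixon
water–fat swaps, Rician noise), other organs, or realistic soft-tissue
texture. Passing phantom tests therefore demonstrates the pipeline's
*contracts* — geometry, fusion, measurement, QC sensitivity — not clinical
segmentation accuracy on real cohort data, which requires the restricted
images and reference segmentations.

## Preprocessing and the 2.5D input

Each station is normalized by clipping the brightest 1% of its intensity
values (per station, over all voxels — stabilising against hot voxels) and
rescaling to [0, 1]. For every axial slice a 2.5D stack is formed from the
slice below, the target slice and the slice above, with a periodic border at
the station ends. In-plane dimensions are zero-padded symmetrically (odd
remainders put the extra column after) to the next multiple of 32, taking
the 224 x 174 acquisition matrix to 224 x 192; the pad widths are recorded
and exactly inverted after prediction. Online augmentation warps stack and
label with one shared smooth displacement field (a 4 x 4 control grid of
clipped Gaussian displacements, bilinearly upsampled; images interpolated
linearly, labels nearest-neighbour). A configurable number of outermost
station slices (default 2 per end) is excluded from training, where
acquisition artefacts concentrate.

## The segmentation network

The network is a compact encoder–decoder: VGG-style two-convolution blocks
with a short residual (identity) connection around the second convolution,
2 x 2 max pooling between stages, a mirrored decoder with nearest-neighbour
upsampling and long skip concatenations, and a 1 x 1 convolution to two
class scores. It maps any H x W x 3 stack to H x W x 2 scores provided H
and W divide by `2^(stages − 1)`. The full-scale widths are
(64, 128, 256, 512, 512); with the package's L − 1 pooling layout this
downsamples by 16, while the slice padding keeps the conservative multiple
of 32 that reproduces the printed 224 x 192 stack size. The residual
placement (around the second convolution of each block, where input and
output widths match) and the absence of batch normalization are package
choices; the forward/backward passes and Adam optimizer are implemented in
C++ (RcppArmadillo, im2col convolutions), so training and inference run on
a single CPU with no external deep-learning runtime.

Training follows an iteration-based schedule with batch size one and
pixel-wise cross-entropy: the reference schedule is 80,000 iterations at
learning rate 1e-4, dropped by a factor of 10 at iteration 60,000 — retained
as `training_config()` defaults. Desk-scale runs in the test-suite use
`width_multiplier = 0.25`, 48 x 48 phantom slices, 2,000 iterations at
1e-3 (dropped at 1,500): about two minutes on one CPU, reaching fused Dice
above 0.99 on held-out phantoms. No pre-trained encoder is shipped —
initialisation is He-normal — but `load_encoder_weights()` loads encoder
parameters from a checkpoint, leaving the decoder untouched.

## Station fusion and measurement

Stations share the in-plane grid and spacing; their origins place them on a
common longitudinal axis (the offset must be an integer number of slices —
no sub-voxel registration or mosaicing correction is attempted). Outside the
overlap each station is copied verbatim. Across the `m` shared slices,
intensities are blended with a midpoint linear ramp (station-B weight
`(j − 0.5)/m`), so weights sum to one, never degenerate to 0 or 1, and each
station dominates toward its own interior. Label *probabilities* — the
network's softmax foreground channel — are blended with the same weights and
thresholded at 0.5, ties mapping to kidney; blending soft outputs rather
than voting on hard labels reduces seam artefacts.

Connected components use face (6-neighbour) connectivity, which resists
single-voxel diagonal bridges into neighbouring mislabelled organs;
components are ordered by size with ties broken by smallest linear voxel
index. The two largest components are the kidneys; the one whose centre of
mass sits at larger column (left–right) coordinate is the subject's left —
a convention the phantom shares. Volume is voxel count times physical voxel
volume; the inter-kidney measurement is the componentwise centre-of-mass
offset and its Euclidean norm. With one component the measurement is
unilateral (side assigned relative to the volume midline, distance absent);
with none it is zero and flagged.

## Algorithmic quality control

The exact cost formulas are the package's normative definitions of the
five ratings:

* **image fusion cost** — mean absolute difference of the normalized water
  signals over all overlap voxels (0 = perfect alignment, 1 = maximal
  disagreement);
* **segmentation fusion cost** — one minus the Dice overlap of the two
  stations' labels on the shared slices (0 when both empty);
* **location cost** — `|z_com − z_mid| / (z_extent/2)` of all segmented
  voxels on the fused grid, in [0, 1]; values near 1 mean the kidneys touch
  the field-of-view edge and may be truncated;
* **smoothness cost** — `mean |A(z+1) − A(z)| / mean A(z)` of the per-slice
  labelled areas over the active slice range, penalising the abrupt
  area jumps characteristic of slice-wise 2.5D failures;
* **scrap cost** — share of labelled voxels outside the two largest
  components, identical to the measurement's scrap fraction.

Flagging is two-staged: stage 1 takes the union of the worst 1% tails of
location and image-fusion cost and the worst 2% tail of segmentation-fusion
cost over the whole cohort; stage 2 recomputes percentiles of smoothness
and scrap cost over the stage-1 survivors and flags their worst 1% tails.
A subject is flagged only when strictly above the type-7 quantile
threshold, so degenerate cohorts with identical costs flag nobody, and
stage-1 flagged fractions obey the union bound (at most 4% under the
default settings). Re-inclusion of small subjects flagged by location alone
is a manual override, not automated.

## Validation metrics

Dice and Jaccard are computed on fused volumes only (the identity
`J = D/(2 − D)` is enforced per subject in the tests); a pair of empty
masks scores 1 by default (configurable to 0). Volume agreement uses the
mean absolute error, the symmetric mean absolute percentage error — the
absolute difference divided by the mean of prediction and reference, per
pair, then averaged, so a 25 cm³ difference at mean 250 cm³ is exactly 10% —
the regression-free coefficient of determination
`R² = 1 − Σ(ref − pred)² / Σ(ref − mean ref)²`, and 95% Bland–Altman limits
of agreement `mean(d) ± 1.96 sd(d)` with `d = reference − predicted`
(sample SD, plain 1.96 multiplier without small-sample correction), so
systematic oversegmentation shifts the interval negative.
`cross_validate()` implements subject-level k-fold validation (classical
k = 8) with an optional training-only extra pool that never enters a
validation fold.

## Numerical choices and degenerate inputs

Constant-intensity stations normalize to zeros with a warning; empty masks
give volume 0, location cost 1 (worst), smoothness and scrap cost 0 with a
reason, and Dice 1 against another empty mask. Quantiles are R's type 7
throughout. Odd padding splits as (floor, ceil). Training, augmentation and
cohort generation derive all randomness from explicit seeds through the R
RNG, so every artefact is byte-reproducible in single-threaded execution.

## Problem sizes used by the test-suite

The suite validates contracts on 48 x 48 x 24 phantoms at (4, 4, 6) mm
(16-slice stations, 8-slice overlap): 20 phantoms for volume recovery, a
100-subject cohort for QC flagging, 2 training + 5 held-out phantoms for
the desk-scale learning check, and a pair of full-scale 224 x 174 x 64
generations for geometry realism. These sizes were chosen so the whole
suite runs in minutes on a single CPU while still exercising every code
path at the acquisition's station layout.

## Known limitations

DICOM series import is not provided (convert to NIfTI first). Fusion
assumes slice-aligned station origins; mosaicing registration is out of
scope, so large inter-station motion is *detected* (QC) rather than
corrected. The QC cost formulas are this package's own normative definitions of the
five described ratings. Phantom realism bounds what the tests can show
about cohort data; the network reaching Dice ≈ 0.99 on phantoms says the
implementation learns and generalises within the phantom family, not that
it would match operator-level accuracy on cohort data.
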