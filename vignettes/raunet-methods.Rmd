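---
title: "Methods: residual-attention U-Net cascade for liver CT segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual-attention U-Net cascade for liver CT segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Thermal ablation (radiofrequency or microwave) of liver tumors is planned and
evaluated on multi-phase contrast-enhanced CT: an arterial phase acquired
~15–25 s after contrast injection and a portal-venous phase at ~50–70 s.
Assessing treatment success requires delineating three structures — the liver,
the pre-treatment tumors, and the post-treatment ablation zone — on both
phases and both timepoints. `raunet` implements a two-stage deep-learning
cascade for this task, together with the preprocessing, training protocol,
lesion-level evaluation statistics, and a synthetic CT phantom generator that
makes the whole pipeline testable end to end on a single CPU with no data
download.

# Preprocessing

CT attenuation is measured in Hounsfield units (HU; water = 0, air = −1000).
Three steps precede every network:

1. **HU clipping** to `[-100, 200]` (inclusive). Liver parenchyma, tumors and
   ablation zones all fall inside this soft-tissue window; clipping removes
   bone, air and contrast-pooling extremes. Clipping is idempotent and is
   applied *before* resampling so interpolation never mixes extreme values
   into the window.
2. **Isotropic resampling** to 1.0 × 1.0 × 1.0 mm³ voxels, trilinear for
   intensity volumes and nearest-neighbour for masks (preserving binarity).
   The output extent per axis is `round(shape × spacing / target)` with ties
   rounded up; the rounding convention matters only at sub-voxel scale.
   Axis order is fixed as (z, y, x) — the slice axis first, because
   abdominal CT is anisotropic through-plane (typically 2 mm slices vs.
   sub-mm pixels).
3. **Intensity normalization**: the affine map of the clip window onto
   `[0, 1]`. The network input scaling is not dictated by the segmentation
   problem itself; a fixed affine map keeps HU semantics (a given tissue
   always lands at the same input value) and is required for stable
   optimisation.

# The residual-attention U-Net

Both network variants share one architecture family, built over 5D tensors
(z, y, x, channel, batch); the 2D slice model is the same machinery with a
singleton slice axis.

* **Encoder**: one residual block per resolution level, 2× max-pooling
  between levels. The 2D model uses 4 levels with channel schedule
  32-64-128-256-512, so a 512×512 slice reaches a deepest feature map of
  32×32×512.
* **Decoder**: learned 2× transposed convolutions, an attention block gating
  each encoder skip connection, channel concatenation, and one residual
  block per level. A final 1×1 convolution with sigmoid activation emits a
  one-channel probability map at input resolution. The 2D model totals 9
  residual and 4 attention blocks.
* **Residual block**: pre-activation — three stacks of batchnorm → ReLU →
  convolution with kernel pattern (1×1, 3×3, 1×1) — plus an identity skip,
  projected by a 1×1 convolution when the channel count changes. The
  internal width is `out_channels / bottleneck_factor`.
* **Attention block**: a trunk branch (one residual block) multiplied by
  `1 + M`, where the soft mask `M` comes from a mask branch that pools the
  skip feature, processes it with its own residual block, restores
  resolution with a learned transposed convolution, reduces with a 1×1
  convolution and applies a sigmoid. The `(1 + M)` form lets the mask
  amplify salient regions without ever suppressing the identity signal.

**Bottleneck calibration.** The block internals admit several readings: a
naive full-width 3×3 triple-stack would put the 2D network at roughly three
times its stated parameter budget of 2.9 million. We fixed the design once:
`bottleneck_factor = 4` with the (1, 3, 1) kernel pattern and the
transposed-conv mask-branch upsampling described above gives 2 926 539
trainable parameters for the full 2D specification — 2.9 M to one decimal.
This calibration is frozen; `scripts/acceptance.R` recomputes the count from
scratch.

**3D variant.** The lesion models take 3D patches of 20×30×30 and 40×60×60
voxels. These extents are not divisible by 2⁴, so the 3D networks use 3
pooling levels (channel schedule 32-64-128-256) and patches are zero-padded
to the next multiple of 8 per axis (20×30×30 → 24×32×32; 40×60×60 →
40×64×64), with predictions cropped back. Padding with zeros (= the clipped,
normalized background floor) is innocuous because the padded voxels never
contribute to the cropped output region's supervision.

# Loss and training protocol

The loss is the soft dice loss
$L = 1 - \frac{2\sum s_\mathrm{true}\, s_\mathrm{pred}}
{\sum s_\mathrm{true}^2 + \sum s_\mathrm{pred}^2}$,
which for binary inputs equals $1 - \mathrm{DSC}$ exactly. During training a
smoothing constant of 1.0 is added to numerator and denominator: background
patches with empty targets are a designed part of the balanced sampling
scheme, and the smoothed loss defines the empty/empty case as 0 with
vanishing gradients instead of 0/0.

Optimisation is Adam at an initial learning rate of 1e-4, up to 1500 epochs,
early stopping after 500 epochs without improvement of the monitored loss,
and plateau-based learning-rate decay: when the monitored loss has not
improved for 20 epochs the rate is multiplied by `lr_factor` (floor 1e-6).
The protocol's stated "reducing the learning rate by a factor of 10%" is
ambiguous between ×0.1 and ×0.9; we default to ×0.1 (the common
reduce-on-plateau convention) and expose the factor as a configuration knob.
The monitored quantity is the validation dice loss when a validation split
exists (default fraction 0.1, seeded), else the training loss; validation
batches are evaluated with batch statistics, like training batches, so the
monitor is comparable across epochs from epoch 1. Batch sizes follow the
full-scale protocol: 10 slices for the 2D model, 72 balanced 3D patches
(36 foreground + 36 background) for the lesion models.

All randomness — weight initialisation, the validation split, shuffling,
patch sampling — derives from explicit seeds, making training runs
bit-reproducible.

**Transfer learning** (`transfer_init()`) copies every weight and batchnorm
statistic from a base model into a new model with an identical architecture
spec; all layers remain trainable. This mirrors the two-step protocol of
pre-training a base model on a public single-phase dataset and fine-tuning
it on local multi-phase data.

# Cascaded inference

1. Preprocess the raw volume (clip → resample → normalize).
2. Segment the liver slice-by-slice with the 2D model; stack and threshold
   at 0.5.
3. Place a 200×300×300 bounding box centred on the liver-mask centroid,
   clamped to the volume. If the tight liver extent exceeds the requested
   box on an axis, the box grows to the extent plus a 5-voxel margin per
   side. Centroid-centring (vs. tight-extent fitting) is our choice; with
   the generous default box the two coincide in practice.
4. Tile the box at each patch scale with 10% overlap, interpreted per axis
   as `round(0.10 × patch_extent)` voxels (2/3/3 and 4/6/6), giving strides
   18×27×27 and 36×54×54. Starts run 0, stride, 2·stride, …, with the final
   start clamped to `box − patch` so the far edge is always covered; edge
   patches are window-shifted rather than padded, keeping their intensity
   statistics natural. For the default geometry this yields exactly 1331
   and 216 patches.
5. Predict each patch, threshold, and stitch by **union**: a voxel is
   foreground iff any covering patch marks it. The same union merges the
   two scales ("overlapping segmented voxels retained and merged").
   Probability averaging before thresholding is available as a
   configuration alternative (`merge = "mean"`).
6. Gate the lesion mask by the liver mask dilated by 2 voxels. Training
   patches are drawn from within the liver, so predictions outside it are
   out-of-distribution; the small dilation tolerates boundary error from
   stage 2 without letting lesions float free in the abdomen.

# Evaluation

* **DSC** `2|RS∩PS| / (|RS|+|PS|)`, defined as 1 for two empty masks.
  Per-case DSCs are aggregated as the median (reported beside the SD).
* **Lesion instances** are connected components under 26-connectivity (the
  clinical notion of "a lesion" never splits a mass that touches
  diagonally). A reference lesion is detected if any predicted component
  shares at least one voxel with it; an IoU-free any-overlap criterion is
  deliberately lenient and is exposed as a minimum-overlap-fraction option.
* **Detection statistics**: sensitivity TP/(TP+FN), precision TP/(TP+FP),
  F1 their harmonic mean, FP/image. Degenerate conventions: sensitivity
  with no reference lesions is undefined (NA, case excluded); precision
  with no predictions is 1 if there are also no reference lesions, else
  NA; F1 is 0 when S + P = 0.
* **Sub-analysis at ≥ 0.5 cm³** (≈ spherical diameter 1 cm, the clinical
  CT detectability limit): the volume filter is applied to *reference*
  lesions and, symmetrically, to predicted components — removing tiny
  predicted specks is what drives the FP/image drop in the sub-analysis.
* **Volumetric agreement**: Pearson r plus Bland–Altman bias and 95%
  limits of agreement (bias ± 1.96 SD of differences) over per-case total
  lesion volumes, computed on the 1 mm isotropic grid.

# The phantom generator

Each phantom case contains a lobed-ellipsoid liver (three overlapping
jittered ellipsoids) at liver-tissue HU inside a soft-tissue body; 1–3
tumors (probabilities 46/63, 11/63, 6/63) as random-aspect ellipsoids fully
inside the liver; and, post-treatment, a larger concentric ablation zone
containing each tumor. Venous-phase tumors are hypodense; arterial-phase
tumors carry an enhancing rim (a shell around the tumor boundary) brighter
than liver; ablation zones are hypodense in both phases. Gaussian HU noise
is added; masks are exact by construction.

**Volume distributions.** Lesion volumes follow truncated log-normals whose
*untruncated* mean and SD equal the configured clinical summary values
(tumors 10.43 ± 18.52 cm³ truncated to [0.06, 82.61]; ablation zones
56.66 ± 36.20 cm³ truncated to [6.76, 200.78]). A log-normal is the natural
right-skewed model for lesion volumes, and the only simple choice whose mean
survives the hard lower truncation essentially unshifted: a normal with SD
larger than its mean, truncated near zero, would inflate the realized mean
by ~85%.

**Geometry at reduced field of view.** The default phantom grid is
96×160×160 at 1 mm — a scaled-down liver field of view chosen so the full
pipeline (including training) runs on one CPU in minutes; the full
200×300×300 bounding-box geometry is still exercised by the tiling tests.
At this scale a 56 cm³ ablation sphere does not always fit inside the
synthetic liver, so lesion placement caps each tumor/ablation pair at the
largest size the liver interior admits around the sampled centre (freshly
drawn volumes are instead re-drawn when the cap would push a tumor below
the clinical 0.06 cm³ floor). The manifest records the sampled target
volumes; each realized case records the achieved voxel volumes.

**Modes.** `"easy"` mode (high contrast, no noise) exists for fast
deterministic training tests; `"realistic"` mode uses moderate contrast and
10 HU Gaussian noise. What an easy-mode phantom cannot show: real livers
have heterogeneous texture, vessels, partial-volume boundaries, breathing
artefacts and neighbouring organs of similar attenuation. Passing tests on
phantoms demonstrates that the pipeline's mechanics (preprocessing, tiling,
stitching, training loop, evaluation) are correct, not that the networks
reach clinical accuracy — that requires the full-scale clinical protocol,
which is out of scope here.

# Scaled-down test conditions

The test-suite's end-to-end check trains reduced-width networks (channel
schedules divided by 8: 4-8-16-32-64 in 2D, 4-8-16-32 in 3D) on an
easy-mode cohort of 8 training and 4 test phantoms at 96×160×160, for 12 /
15 / 6 epochs (liver / small scale / large scale) with learning rate 3e-3 —
a deliberately small fraction of the 1500-epoch full protocol, sized so the
whole run finishes in roughly ten CPU-minutes. Against the exact phantom
truth it verifies liver DSC ≥ 0.8 and per-lesion tumor sensitivity ≥ 0.7 on
the held-out phantoms; these thresholds are our desk-scale sanity bars, far
below what the full protocol reports on clinical data, and deliberately so.

# Numerical choices and edge cases

* Clip bounds inclusive; binarisation threshold 0.5 inclusive (`≥`).
* Batchnorm: per-channel batch statistics during training, running
  averages (momentum 0.1) at inference; ε = 1e-5.
* He initialisation for convolutions; batchnorm starts at identity.
* Improvement threshold for plateau/early-stopping: 1e-6 absolute.
* Resampling coordinates are voxel-centre aligned and clamped at the grid
  boundary (no extrapolation).
* `dice_loss(0, 0) = 0` by convention (two empty segmentations agree);
  `dsc(0, 0) = 1` likewise.
* Empty liver mask at inference is an error ("no liver found") rather than
  a silent empty result.

# Known limitations

* No spatial registration between phases is attempted; each phase is
  segmented independently, as in the two per-phase model protocol.
* The convolution engine is CPU-only and double-precision; it is sized for
  desk-scale verification, not full-scale training.
* DICOM reading, contrast-phase detection from metadata, and
  minimal-ablative-margin computation are out of scope.
* The phantom emulates contrast and geometry, not CT physics (no beam
  hardening, perfusion kinetics, vessels or neighbouring organs).
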