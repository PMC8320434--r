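# raunet

Two-stage, multi-scale **residual-attention U-Net** pipeline for segmenting
the liver, liver tumors and thermal-ablation zones in multi-phase
contrast-enhanced abdominal CT — with the full training protocol, cascaded
inference, lesion-level evaluation statistics, and a seeded synthetic CT
phantom generator so everything is exercisable end to end on one CPU,
without any clinical data.

## Who this is for

Researchers in medical image analysis who need a transparent, dependency-light
reference implementation of the liver → lesion segmentation cascade:
Hounsfield-unit preprocessing, slice-wise 2D liver segmentation, liver
bounding-box extraction, overlapping multi-scale 3D patch tiling and
stitching, dice-loss training with transfer learning, and detection /
volumetric-agreement evaluation. The convolution engine (2D/3D convolutions,
batchnorm, transposed convolutions, Adam, exact backprop) is implemented in
R + RcppArmadillo inside the package.

## The method in brief

**Architecture.** An encoder–decoder U-Net whose convolution layers are
pre-activation bottleneck *residual blocks* (3 stacks of batchnorm → ReLU →
conv, kernels 1–3–1, internal width `out/4`, identity skip) and whose skip
connections pass through *attention blocks*: a trunk branch gated as
`(1 + M) · trunk` by a soft mask `M` from a pooled encode–decode branch.
The 2D liver model (4 levels, channels 32–512; deepest feature 32×32×512
for a 512×512 slice) has 9 residual blocks, 4 attention blocks and
2.9 million trainable parameters. The 3D lesion models (3 levels, channels
32–256) run on patches of 20×30×30 and 40×60×60 voxels, zero-padded to
multiples of 8.

**Loss.** Soft dice loss `1 − 2·Σ(s_t·s_p) / (Σs_t² + Σs_p²)`, which equals
`1 − DSC` for binary masks. Adam (lr 1e-4), up to 1500 epochs, early
stopping after 500 without improvement, learning rate ×0.1 on a 20-epoch
plateau.

**Cascade.** clip HU to [−100, 200] → resample to 1 mm isotropic →
normalize → 2D liver segmentation per slice → 200×300×300 bounding box on
the liver centroid → per scale: tile with 10% overlap (1331 + 216 patches),
predict, stitch by union → merge scales by union → gate by the 2-voxel
dilated liver mask.

**Evaluation.** Median DSC; lesion-level TP/FN/FP under 26-connectivity and
any-voxel overlap; sensitivity, precision, F1, FP/image; the ≥ 0.5 cm³
sub-analysis; Pearson r and Bland–Altman limits of agreement for volumes.

## Worked example

```r
library(raunet)

# a seeded synthetic cohort: 12 phantoms, 8 train / 4 test
params <- phantom_params(mode = "easy", seed = 101)
cohort <- generate_cohort(12, params, split = c(train = 8/12, test = 4/12))
case <- realize_case(cohort, "case001")
case$volumes$pre_venous
#> <ct_volume> 96x160x160 voxels, spacing 1x1x1 mm, phase=portal_venous, timepoint=pre
#>   HU range [-60.0, 120.0]

# the full-size 2D architecture reproduces the published parameter budget
m <- build_network(network_spec_2d())
count_parameters(m)
#> [1] 2926539     # 2.9 M

# dice loss and DSC are exact complements on binary masks
a <- case$masks$tumor$voxels
dice_loss(a, a); dsc(a, a)
#> [1] 0
#> [1] 1

# the published tiling geometry: 10% overlap in a 200x300x300 box
g <- tile_patches(bounding_box(c(0,0,0), c(200,300,300)),
                  patch_spec(c(20,30,30), 0.10))
nrow(g$starts)
#> [1] 1331
```

Training and cascaded inference, from the shell:

```sh
inst/cli/raunet phantom  --n 12 --seed 101 --mode easy --out cohort/
inst/cli/raunet train    --data cohort/ --task liver --out ckpt/liver.rds \
                         --epochs 15 --seed 4
inst/cli/raunet train    --data cohort/ --task tumor --out ckpt/tumor.rds \
                         --epochs 15 --seed 4
inst/cli/raunet infer    --case cohort/case011 --liver-ckpt ckpt/liver.rds \
                         --lesion-ckpts ckpt/tumor_scale1.rds,ckpt/tumor_scale2.rds \
                         --out pred/case011
inst/cli/raunet evaluate --pred pred/ --truth cohort/ --min-volume 0.5 \
                         --out report/
```

`report/evaluation_summary.json` then holds the median DSC, detection
statistics (all lesions and the ≥ 0.5 cm³ sub-analysis) and Bland–Altman
agreement; `report/evaluation_per_case.csv` the per-case rows.

## Scope

Desk-scale verification of the method's mechanics. Full-scale training on
clinical or public challenge data (multi-GPU, 1500 epochs) and clinical
interpretation (ablative-margin assessment) are out of scope; see the
methods vignette (`vignettes/raunet-methods.Rmd`) for design decisions and
limitations.
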