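# tauseg

Coarse-to-fine segmentation of the pancreas, pancreatic ductal
adenocarcinoma (PDAC) and the superior mesenteric vessels in volumetric
CT, driven by classic texture descriptors fused into attention-gated
networks. The package is aimed at researchers who want a fully testable,
CPU-scale implementation of this pipeline: every stage runs end to end on
generated CT-like phantoms with analytic ground truth, so no imaging data
or GPU is required to exercise, test or extend it.

## What is implemented

**Coarse stage (localization).** Volumes are clipped to the
[0.5, 99.5] intensity percentiles and min-max normalized. A
rotation-invariant 3D local binary pattern (LBP) transform encodes each
voxel by spherical-harmonic band energies of its spherical
neighbor-difference sample (plus kurtosis),

    E_l(v) = sum_m [ (1/J) * sum_j f_j(v) Y_lm(d_j) ]^2 ,  l = 0..L,

computed over J = 26 directions at radius 2. A five-block 3D CNN
classifies 64^3 sub-volumes of the scalar-encoded map as
pancreas-containing or background; at test time a sliding window is
classified and the gravity center of the positive windows places a
fixed-size bounding box.

**Fine stage (segmentation).** Slices of the cropped region pass through
an Attention U-Net and a TAU-Net — the same encoder-decoder with
attention gates

    phi = sigmoid( psi( ReLU( W_l x_l + W_h x_h ) ) ),   x_l_hat = phi * x_l,

where TAU-Net concatenates texture features onto the gating signal:
dense SIFT (stride 4) at the scale-4 skip and the LBP scalar slice at the
last skip. A hybrid fuser — one 3x3x3 convolution over the six stacked
probability maps with per-voxel renormalization — merges the two
networks into the final labeling.

**Loss.** `0.33 * WPCE + 0.33 * GDL + 0.33 * BF1`: background-ratio
weighted cross entropy, generalized Dice with inverse-squared-volume
class weights, and a differentiable boundary-F1 built from max-pooled
boundary bands.

**Evaluation.** Dice (global and per case), recall, precision, and the
95th-percentile Hausdorff distance in mm.

All networks run on a compact, hand-written CPU CNN toolkit (Rcpp
kernels, im2col + BLAS convolutions, Adam with polynomial decay);
no deep-learning framework is required.

## A worked example

```r
library(tauseg)

# a 20-case phantom cohort with a random 70-30 split
man <- generate_cohort(20, phantom_config(), split_fraction = 0.7,
                       seed = 101, out_dir = "cohort")

# train localizer, both segmentation networks and the fuser
fit <- fit_cascade(man, widths = c(8, 16, 32, 64, 64), steps = 300,
                   batch_size = 2, lr = 1e-3,
                   loc_config = localizer_config(epochs = 3, n_per_class = 2,
                                                 widths = c(2, 4, 8, 8, 8)),
                   loc_cases = 10, seed = 7)

# segment a held-out case and score the tumor
te  <- man[man$split == "test", ][1, ]
v   <- read_volume(te$image_path)
lab <- read_labels(te$label_path)
pred <- predict_volume(v, fit$localizer, fit$net_a, fit$net_b, fit$fuser,
                       fit$box_size, stride_xy = 25, stride_z = 20)
score_case(lab, pred, class_id = 2, spacing_mm = lab$spacing_mm)
```

On the seeded cohort above this prints, for the first test case,

```
  class_id      dice    recall precision  hd95_mm  tp size_u size_v
1        2 0.6947505 0.5845147   0.85623 3.162278 536    917    626
```

that is: the fused cascade recovers the low-contrast tumor of a held-out
phantom with Dice about 0.69 and a 95% Hausdorff distance of about 3 mm
(case-level values vary a few points across seeds and cases; the
acceptance run below, on its own seed-1 cohort, pools to a tumor Dice of
0.644 over the test split). The detected
bounding box is attached as `attr(pred, "box")`, and localization
coverage — the fraction of pancreas voxels inside the predicted box —
runs above 95% on the test split.

A thin command-line front end over the same functions is installed at
`inst/cli/tauseg.R` (`synth`, `preprocess`, `texture`, `evaluate`).

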