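---
title: "Coarse-to-fine texture-attention segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine texture-attention segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) is close to isointense with the
surrounding parenchyma on portal-venous CT, and the pancreas itself fills
only a small corner of a 512 x 512 x L scan. `tauseg` implements a
two-stage answer to both difficulties: a **coarse stage** that finds the
pancreas-containing region by classifying texture-encoded sub-volumes,
and a **fine stage** in which two attention-gated encoder-decoder
networks segment background/pancreas/tumor on 2D slices of the cropped
region, followed by a small 3D network that fuses their probability maps.
The same fine-stage machinery, initialized from the PDAC networks, is
fine-tuned for the superior mesenteric artery and vein (SMA/SMV), the
vessels whose involvement determines resectability.

## Coarse stage: 3D-LBP sub-volume classification

Raw intensities are clipped to the [0.5, 99.5] percentiles of each volume
and min-max normalized to [0, 1]. The localizer never sees intensities
directly: each 64^3 sub-volume is represented by a rotation-invariant 3D
local binary pattern (LBP) map. For every voxel we sample intensity
differences at 26 quasi-uniform directions on a sphere of radius 2
voxels, project them onto real spherical harmonics up to order L = 2, and
keep the per-band energies (sums over m of squared coefficients), plus
the kurtosis of the difference sample as a non-Gaussianity channel. Band
energies are invariant under any rotation that permutes the direction
set; the 26-direction design (the 3 x 3 x 3 shell) is closed under all 24
axis-aligned 90-degree rotations, which is what the test suite verifies
to 1e-6. The displayed/classified scalar volume is the min-max-normalized
band-energy sum; the multi-channel invariants are retained on the map
object for configurations that want them.

Design choices the sources left open, decided here once:

* **Radius 2, order 2, 26 directions.** Small support fits the small
  glandular patterns being described; 26 directions are the smallest
  symmetric design with exact 90-degree closure that supports L = 2
  ((L+1)^2 = 9 coefficients).
* **Kurtosis of a zero-variance sample is 0**, with the zero test guarded
  by a floating-point floor relative to the intensity scale, so constant
  volumes have an exactly zero descriptor.
* **Payloads are cropped from the full-volume scalar map** rather than
  re-encoded per window, so training windows and sliding-window inference
  see identically normalized features and the map is computed once per
  volume.

The classifier is a five-block 3D CNN (two or three 3 x 3 x 3
convolutions per block, stride 1, 2 x 2 x 2 max pooling), trained with
cross entropy, Adam (base learning rate 0.01) and polynomial decay
`lr0 * (1 - t/T)^0.1`. Two deliberate deviations: the stated pooling
padding of the source design is geometrically inconsistent with stride-2
2^3 pooling of a 64^3 input, so pooling is unpadded; and normalization is
per-sample (instance) rather than batch statistics, because the toolkit
processes samples singly — per-sample normalization is deterministic at
train and inference time, which makes every test reproducible bit for
bit. Channel widths are configurable; the desk-scale defaults are small
because the foreground/background texture contrast is an easy decision
problem.

At test time a sliding window (default strides: 50 in-plane, 20 axial for
512-grids) classifies every window; the unweighted mean of the centers of
foreground windows — the gravity center — is the detected pancreas
center, and a fixed-size box (dataset-level maximum organ extent plus a
16-voxel margin) is clamped into the volume around it. An end-aligned
window is appended per axis so the grid covers the full extent. On the
desk-scale 160 x 160 x 96 phantoms the evaluation stride is 25/20: the
gravity-center estimate is quantized by the window grid, and a 50-voxel
stride on a 160-voxel axis leaves only three samples — too coarse for the
box slack the coverage criterion allows.

## Fine stage: attention U-Net and TAU-Net

The cropped region is cut into axial 2D slices (single-channel; no 2.5D
stacking). Both networks share a five-step encoder (two 3 x 3
convolutions + normalization + ReLU per step, 2 x 2 max pooling between
steps, scales 1-16) and a transposed-convolution decoder. Input sizes
must be divisible by 2^5 — the build-time contract — and the class head
is a 1 x 1 projection followed by a per-pixel softmax over background,
pancreas and tumor.

**Attention gates.** Each skip connection is rescaled by a coefficient
map `phi = sigmoid(psi(ReLU(W_l x_l + W_h x_h)))` computed from the skip
features `x_l` and the decoder's gating signal `x_h` (already upsampled
to the skip grid). We implement the standard additive gate: separate
1 x 1 projections of both inputs into an intermediate width of half the
skip channels, and a single-channel scoring projection. The equations'
two statements of the gate differ in whether the inputs are transformed;
we follow the more specific transformed form, which is also the cited
gate design.

**Texture attention blocks.** TAU-Net replaces two gates: at the scale-4
skip (the second up-sampling stage, feature maps a quarter of the input
size) the gating signal is concatenated with a dense SIFT tensor, and at
the scale-1 skip (last layer) with the LBP scalar slice. Dense SIFT is
computed on a stride-4 grid — matching the scale-4 feature grid — with
the standard 4 x 4 cells x 8 orientations geometry, cell size equal to
the stride, L2 normalization with clip(0.2)-renormalize, zero vectors on
flat patches. Descriptor maps are standardized per channel (zero mean,
unit variance over the image) before fusion so the raw histogram scale
cannot dominate the learned features; they are constants with respect to
the optimizer (no gradients flow into them). The block concatenates the
gated skip with the texture-enriched gating signal, so texture
information propagates into the decoder; the literal equation
concatenates with the un-enriched signal instead, and the standalone
`texture_attention_block()` exposes both the gated features and the
concatenated output so either reading can be composed.

With the texture tensors zeroed and the weights acting on texture
channels zeroed, TAU-Net is functionally identical to the Attention
U-Net of the same widths; `transfer_aunet_to_tau()` constructs exactly
this configuration and the suite asserts equality to 1e-6.

**Hybrid fuser.** The two networks' per-class probability maps are
stacked slice-wise into a six-channel 3D grid and passed through a single
3 x 3 x 3 convolution (6 -> 3 channels) with per-voxel normalization to
probabilities, so each voxel is relabeled using its neighborhood along
all three axes. Normalization is ReLU-then-renormalize rather than
softmax: with the average-and-pass-through initialization (center tap
0.5/0.5 per class) the fuser is then an exact identity on agreeing
inputs, a property softmax cannot have and one that makes the fuser's
behavior testable before training. The fuser consumes probabilities, not
logits, and is trained with cross entropy.

## The composite loss

Three imbalance-aware terms, combined as `0.33 L1 + 0.33 L2 + 0.33 L3`
with the weights taken literally (they do not renormalize to 1):

* **WPCE** — pixel-wise cross entropy with the background weight 1 and
  each foreground class weighted `n_B / n_c`, computed per batch; a class
  absent from the batch gets weight 0 with a warning.
* **GDL** — generalized Dice loss with inverse-squared-volume weights
  `W_c = 1 / (sum_i U_ic)^2` and smoothing `eps = 1e-5`; empty classes
  get weight 0 (the printed `1/0^2` is undefined). The published
  denominator's inner index is a typo read as a sum over all voxels.
  With the smoothing term in both numerator and denominator the value at
  perfect overlap is an O(eps) negative number; it is clamped at 0 so the
  loss stays in [0, 1].
* **Boundary-F1** — boundary bands built by max-pooling: the inner band
  is `max_pool(1 - U, theta0) - (1 - U)`; extended bands apply a second
  max-pool of size `theta`. Precision is the fraction of the predicted
  band inside the extended true band, recall vice versa, and the loss is
  `1 - 2PR/(P + R)`. Defaults `theta0 = theta = 3`; `theta` can be raised
  to the minimal inter-segment distance when a batch has several
  segments. The prediction enters as its soft values everywhere — the
  max filters route gradients to their argmax — so the loss passes
  central-difference gradient checks at 1e-3, which a straight-through
  binarization cannot; this is the package's reading of "differentiable
  version". Degenerate cases: an empty ground-truth boundary skips the
  class with a warning; bands that miss each other's extensions entirely
  (P = R = 0) score loss 1.

Max-filter windows are clipped at image borders (no padding value), and
the dilation-based oracle in the test suite uses the same convention; a
filled mask therefore has an empty boundary, and a mask pixel in an image
corner with only foreground in-image neighbors is not boundary.

## Training protocols

Segmentation networks train with Adam and polynomial decay; the reference
base learning rate for full-scale runs is 5e-5 with batches of 10 slices
and rotation/flip/shift augmentation (ranges here: +/-15 degrees,
+/-10% shift — the operations are specified, the magnitudes are ours).
The ambiguous printed rate "5 x 10e-5" is read as 5e-5. Vessel
fine-tuning reinitializes the class head for {background, SMA, SMV},
keeps all backbone weights, expands the training set 12-fold by
translation/flip/rotation, and trains at 1e-5 for 30 epochs; the
composite loss is reused since no separate vessel loss is stated.

## The phantom generator

Every quantitative claim in the tests is computed on synthetic CT-like
phantoms: a textured ellipsoidal pancreas (semi-axes 20/12/10 mm), an
embedded tumor sphere (radius 6 mm) at contrast -30 against pancreas
tissue of +80, background at -50, two bright tubular vessels, Gaussian
noise (SD 10), and band-limited multiplicative intra-organ texture
(coarse-grid noise, linearly upsampled; descriptors on constant regions
would be degenerate). Shapes are rasterized by testing voxel centers
against the analytic surfaces, so labeled voxel counts are recoverable
exactly by enumeration — that is what the geometry tests check. The
desk-scale default grid is 160 x 160 x 96 at 1 mm spacing: large enough
in-plane that the organ is a small fraction of the field of view (the
premise of the coarse stage, and a requirement for zero-overlap
background sub-volumes to exist at all with 64^3 windows); a
512 x 512 x 96 anisotropic preset mirrors the full-scale geometry.
Intensities are arbitrary CT-like units chosen so the clip/normalize path
is non-trivial; no intensity statistics were stated for the real data.

What the phantoms do **not** emulate: anatomical shape variability,
duodenum/vessel abutment, partial-volume effects at interfaces,
multi-phase contrast, or inter-scanner intensity shifts. Passing the
desk-scale study therefore demonstrates that the pipeline's mechanics —
localization, texture fusion, loss behavior, ensemble fusion, metric
accounting — are correct, not that the printed clinical accuracy would be
reproduced on patient data.

## Desk-scale study sizes and numerical choices

The acceptance study uses a 20-case cohort (70-30 split), localizer
widths (2, 4, 8, 8, 8) trained 3 epochs on 2 sub-volumes per class from
10 training cases, segmentation widths (8, 16, 32, 64, 64) trained 300
Adam steps (batch 2, learning rate 1e-3 — at desk scale a 5e-5 rate
cannot move a random initialization within a few hundred steps), every
second slice of the ground-truth-centered crop (all slices, not only
tumor-bearing ones: a network that never sees empty slices hallucinates
tumor on them), and a fuser trained 60 steps from the average
initialization on two training cases. The single-case overfit check uses
every slice of one crop with batch 4 at rate 3e-3. These sizes were
chosen once as the smallest configuration a practitioner would call a
meaningful rehearsal of the full protocol. Label ties in the final
argmax are broken toward the first class so predictions are bit-for-bit
reproducible.

Other numerical conventions: voxel indexing is 0-based with half-open
boxes; percentiles use the default type-7 quantile; probabilities are
clamped at 1e-7 inside logs; Adam uses (0.9, 0.999, 1e-8); the Hausdorff
surface is the set of mask voxels with a 6-connected background
neighbor, distances pool both directions and take the type-7 95th
percentile in mm; "global Dice" pools voxel counts over cases before the
ratio, "per-case Dice" averages case-level values. Per-case Dice of an
empty-truth/empty-prediction case is 1; empty truth against a non-empty
prediction scores 0.

## Known limitations

* The CNN toolkit is CPU-only and sized for desk-scale experiments;
  full-resolution training at published widths is out of its intended
  range.
* Normalization layers are per-sample; batch statistics are not
  implemented.
* The localizer's gravity center inherits the window-grid quantization;
  very coarse strides on small volumes bias the estimate.
* Boundary-F1 gradients are subgradients at max-filter ties (measure
  zero under continuous predictions).
* The vessel phantom's tubes are parallel sinusoids — sufficient for
  disjointness and fine-tuning mechanics, not for vascular geometry.
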