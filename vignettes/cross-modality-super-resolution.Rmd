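---
title: "Cross-modality super-resolution of 3D volumes: models, phantoms, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality super-resolution of 3D volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-resolution volumetric imaging of the mouse brain is abundant in optical
modalities (serial two-photon auto-fluorescence atlases at 25 µm isotropic)
but scarce in MRI, where signal-to-noise limits preclinical acquisitions to
roughly 100–200 µm. Super-resolution (SR) networks need large
high-resolution training sets, which exist for the optical contrast but not
for MRI. `voxsr` implements and studies one practical answer: train
patch-based 3D SR networks on a high-resolution structural contrast, then
adapt them to a different contrast by freezing most layers and fine-tuning
the last few on a handful of target volumes.

Because the package must be testable without external downloads, it ships a
phantom simulator that reproduces the *statistical* situation of that study:
a structural "AF-like" contrast with features at several spatial scales, a
companion "T2w-like" contrast strongly correlated with it (r ≈ +0.72), and
an "FA-like" contrast that is only partially explained by it (r ≈ −0.69)
because part of its signal comes from local gradient orientation rather than
intensity.

## The pipeline

1. **Simulate** (`generate_phantom()`, `derive_modality()`,
   `generate_dataset()`): co-registered multi-modality volumes in [0, 1].
2. **Degrade** (`block_average()`): acquisition at lower resolution is
   simulated by boxcar block averaging — each coarse voxel is the mean of
   its factor³ block, with no anti-alias filter, matching how down-sampled
   training data are produced from the native volumes.
3. **Pre-upsample** (`cubic_upsample()`): the network input is always the
   low-resolution volume brought back onto the high-resolution grid by
   separable Catmull–Rom tricubic interpolation, so SR networks are
   shape-preserving and learn only the residual detail.
4. **Patchify** (`extract_patches()`, `sample_patches()`): fixed-size cubes;
   random origins for training (the protocol fixes counts, not locations),
   a clamped raster lattice for inference.
5. **Train** (`train()`, `train_gan()`): Adam (lr 0.001, β₁ 0.9, β₂ 0.999,
   ε 1e-8), MSE loss, Glorot-normal init, early stopping on a validation
   split, best weights restored.
6. **Adapt** (`fine_tune()`): freeze all but the last *n* layers (default 3,
   in forward order) and resume training on the target contrast.
7. **Evaluate** (`rmse()`, `ssim()`, `effective_resolution()`,
   `paired_ttest()`, `welch_anova()`, `pearson_correlation()`).

```{r}
library(voxsr)

ds <- generate_dataset(phantom_config(seed = 1, grid_size = 48, n_volumes = 5))
vols <- lapply(ds$volumes, `[[`, "AF_like")
plan <- resample_plan(25, 50)               # LR 50 um -> HR 25 um

pairs <- lapply(vols[1:4], function(v) make_lr_hr_pair(v, plan))
ps <- sample_patches(pairs, p = 7, n = 400, seed = 1)
net <- build_resnet(model_spec("ResNet", n_res_blocks = 2, channels = 8,
                               input_edge = 7), seed = 1)
model <- train(net, ps, train_config(max_epochs = 30, early_stop_patience = 15,
                                     batch_size = 8, seed = 1))

lr <- block_average(vols[[5]], 2)
sr <- apply_sr(model, lr, factor = 2)
rmse(sr, vols[[5]]); ssim(sr, vols[[5]])
```

## The network families

All three families operate on p³ single-channel patches, use 3×3×3 kernels
with mirror same-padding, and are fully convolutional (shape-preserving for
any p at least the kernel size).

* **cCNN** — three convolutions (channel widths 64, 32, 1 at reference
  scale) with ReLU after the first two and a linear output. The ReLU
  placement follows the classical SR-CNN lineage; the final layer is linear
  because the target is a real-valued intensity.
* **ResNet** — a head convolution to the working width, then residual
  blocks (conv → ReLU → conv, identity skip, ReLU; reference 10 blocks × 64
  channels), then a tail convolution back to one channel. A **global skip**
  adds the input to the output, so the network predicts the HR − LR
  residual; the all-zero-weight network is exactly the identity, which both
  accelerates convergence and provides a clean test anchor. The source
  description of the residual block ("two convolutions, two ReLU with one
  additional layer") is ambiguous about whether the second ReLU precedes or
  follows the skip addition; we place it after the addition, the standard
  construction, and read the "additional layer" as the skip-add itself.
* **GAN** — the ResNet as generator; the discriminator is a residual trunk
  of the same depth and width followed by global average pooling, one dense
  unit and a sigmoid, trained on binary cross-entropy real-vs-generated.
  The generator loss is MSE + w · adversarial; the source work does not
  state w, and we default to 1e-3 so that the adversarial term perturbs
  rather than dominates. With w = 0 the generator trajectory reduces
  exactly to plain MSE training, which the tests exploit.

No batch normalization is used anywhere (the reference architectures have
none). Layer order is the forward order; "the last three layers" of the
2-block desk-scale ResNet are the second block's two convolutions plus the
tail convolution.

## Optimization choices

* **Early stopping** reads "validation loss not decreasing for *patience*
  epochs" as: no new strict minimum within the window. The initial weights
  participate as an epoch-0 baseline and the best-validation weights are
  restored, so training (and in particular fine-tuning, which starts from a
  converged network) can never return something worse than its start on the
  validation split.
* **Validation split** is at the volume level whenever patches from more
  than one volume are present: overlapping patches from one volume never
  straddle the split, which would leak training content into validation.
* **Normalization** is per whole volume (min–max to [0, 1]), never per
  patch — per-patch scaling would make recombined volumes scale-
  inconsistent. Training targets are scaled with their input volume's
  (min, max) so that inference, which can only know the input's range,
  inverts the same map.
* **Determinism**: every stochastic choice (initialization, splits,
  shuffling, patch origins) flows from explicit integer seeds; identical
  seeds reproduce identical weights bit for bit.

## The phantom generator

A phantom is a sum of (a) band-limited Gaussian random fields — white
noise convolved with a difference of Gaussians (sigma, 2 sigma) at each
configured correlation length (sigma = scale / 2 voxels at the native
voxel size), so each scale occupies its own spectral band and volumes
carry genuinely resolution-specific structure — and (b) a
piecewise-constant Voronoi partition (about 30 cells on a 64³ grid, count
scaling with volume) whose region values are uniform draws. Band-limited
fields matter for the resolution-matching study: with plain low-pass
fields the scales overlap spectrally, block-averaged versions of the
content become nearly self-similar, and networks trained at different
resolution pairs become interchangeable. The Voronoi
edges are softened with a kernel a quarter the width of the finest
configured scale: when fine scales are requested the edges stay sharp and
factor-2 coarsening genuinely destroys detail; a phantom with a single very
coarse scale survives a down/up round trip almost unchanged. Defaults
(scales 400, 100, 50 µm at 25 µm voxels) give noticeable spectral energy
beyond a quarter of the Nyquist frequency, so super-resolution has real
content to recover.

Companion contrasts are built by closed-form mixing of standardized fields:
a monotone intensity transform of the source (T2w-like) or the source plus
a normalized directionally-weighted gradient-magnitude feature (FA-like),
plus smoothed independent noise, with the mixing weight solved so the
voxel-wise Pearson correlation with the source hits the target *exactly*
(empirically orthogonalized components; the final [0, 1] rescale is affine
and leaves r unchanged). The FA-like gradient feature makes part of that
contrast depend on local orientation rather than on source intensity — the
property that limits direct cross-modality transfer. What the phantoms do
**not** model: mouse-brain anatomy, Rician MRI noise, registration error,
intensity non-uniformity. Conclusions from passing tests are therefore
about the *mechanics* of the pipeline and the *relative* orderings of
methods under controlled statistics, not about absolute performance on real
data.

## Effective resolution by decorrelation

`effective_resolution()` estimates the highest spatial frequency carrying
correlated signal. For an image with Fourier transform F, the decorrelation
value at mask radius r (a normalized frequency) is the normalized real
cross-correlation between F and its unit-modulus phase-only version
low-pass-masked at r. Curves are computed for 50 radii, repeated under 10
Gaussian high-pass pre-filters (sigmas geometrically spaced over normalized
frequencies 0.15–1) plus a refinement pass around the best peak. A local
maximum is accepted when the curve later drops at least 0.001 below it
(monotone growth up to the Nyquist edge registers as an endpoint peak); the
cut-off K is the highest accepted peak frequency, and the effective
resolution is voxel size / K — the formula used by the study this package
replicates. Volumes are analysed slice-wise (median K over the five central
slices) because the underlying estimator is two-dimensional; a spherical-
mask 3D variant is available behind `use_3d = TRUE`. White noise resolves
at the voxel scale (K near 1); blurring lowers K monotonically.

## The desk-scale experiments

`run_network_comparison()`, `run_resolution_matching()` and
`run_transfer()` replicate the three studies at sizes a laptop CPU handles
in minutes, with every repetition seeded and regenerable:

* 48³ phantoms at 25 µm with scales 400/100/50 µm; 4 training volumes, 2
  held-out test volumes per repetition, 5 repetitions. The
  multi-resolution study uses 64³ phantoms with two well-separated bands
  (800 and 150 µm): the 150 µm band is comfortably restorable at the
  matched 100→50 µm pair (about 1.5 voxels on the 50 µm grid), already
  sub-voxel — hence mostly destroyed — at the coarser 200→100 µm pair,
  and trivially smooth at the finer 50→25 µm pair, so the three training
  resolutions genuinely pose different restoration problems.
* 2-block, 8-channel ResNet; 8-4-1 cCNN; 7³ patches, 400 training patches,
  batch size 8, validation fraction 0.25.
* Per-family epoch budgets (cCNN 150, ResNet 30): the plain CNN must first
  learn the identity map that the ResNet's global skip provides for free,
  so it needs a far longer budget to reach its plateau; both budgets sit
  well past the point where their validation loss flattens.
* Transfer: 6 target-modality volumes for fine-tuning (the reference
  protocol's count), 600 fine-tuning patches, 40 epochs at a reduced step
  size (5e-4) — the standard choice when adapting a converged network —
  with the last 3 layers trainable.

The acceptance surface is the *qualitative orderings* (ResNet ≤ cCNN, both
better than cubic at matched resolution; matched-resolution training best;
fine-tuning better than direct cross-modality application; direct
application better than cubic on the highly correlated contrast), not the
absolute numbers of the original study, which depend on real optical and MRI
data we neither ship nor require.

## Known limitations

* Plain-ReLU residual networks can suffer a dying-ReLU collapse under
  aggressive early Adam steps: the trunk's activations die, the global
  skip makes the network exactly the identity map, and the loss freezes at
  the cubic-baseline level. At desk scale this hits roughly one seeded
  repetition in five; early stopping (with the initial weights as the
  epoch-0 baseline) then returns the identity rather than something worse,
  and the affected repetition carries no ordering information. The
  multi-seed design absorbs this.

* The engine is CPU-only and double-precision; reference-scale settings
  (10 blocks × 64 channels, 21³ patches, 20 000 samples, 1000 epochs) are
  expressible but impractical without hardware acceleration.
* The GAN is trained with a fixed adversarial weight; no scheduling or
  spectral normalization, so very long adversarial runs can collapse (the
  history carries a warning heuristic).
* Correlation calibration is exact only voxel-wise and unmasked; masked or
  regional calibration is not implemented.
* The decorrelation estimator assumes roughly isotropic content within a
  slice; strongly anisotropic voxels would need per-axis treatment.
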