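---
title: "Stable mitochondria segmentation in EM volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable mitochondria segmentation in EM volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emseg)
```

## The problem

Volume electron microscopy (FIB-SEM, ssEM) resolves mitochondria at
nanometre scale, and their automated semantic segmentation — a per-voxel
binary decision, mitochondrion versus background — is a standard
quantification step in connectomics and cell-biology pipelines. Published
results on the common benchmarks are driven as much by the machinery *around*
the network (patch sampling, tiled inference and stitching, test-time
ensembling, morphological post-processing) as by the architecture itself, and
repeated training runs of one configuration spread noticeably because
training is stochastic. `emseg` therefore implements the whole workflow — a
family of small encoder–decoder networks plus sampling, reconstruction,
post-processing, metrics, and a repeated-run stability harness — as one
coherent, fully seeded package.

## The architectures

All models are U-Net variants: an encoder of processing blocks separated by
2× max pooling, a bottleneck, and a mirrored decoder using 2×2 transposed
convolutions (kernel = stride = 2, the shape-preserving mirror of the
pooling) with skip connections concatenated at each level, ending in a 1×1
convolution and a sigmoid. A *processing block* is either

* a **convolutional block** — two 3×3(×3) convolutions, each followed by the
  activation and dropout; or
* a **full pre-activation residual block** — the same two convolutions with
  activation *before* each convolution and an identity shortcut (1×1
  projection whenever the channel count changes).

Optional components:

* **Attention gates** on skip connections: 1×1 projections of the skip
  features and of the gating signal (the decoder features immediately after
  upsampling at the same level) are added, passed through ReLU, projected to
  one channel, squashed by a sigmoid and multiplied onto the skip features.
  The internal projection width equals the skip channel count.
* **Squeeze-and-excitation (SE) blocks** after processing blocks: global
  average pooling, a two-layer gating network (reduction ratio 8, ReLU then
  sigmoid) and channel-wise rescaling. The default placement is everywhere
  except the bottleneck.
* **Batch normalisation** is available as a flag but off by default — in the
  ablation that motivated these presets it *decreased* performance.

The tuned presets (`preset_spec()`): 2D nets have four levels with
16/32/64/128 filters and a 256-filter bottleneck, dropout rising
0.1/0.1/0.2/0.2/0.3 into the bottleneck and mirrored on the way up, ELU
activations, He-normal initialisation. 3D nets use three levels
(28/36/48 filters, 64 bottleneck); the 3D residual net goes one level deeper
(28/36/48/64, 80 bottleneck). For anisotropic stacks the `*_aniso` presets
keep three levels and never pool the Z axis. Convolutions are "same"-padded
and carry biases; the binary head has one output channel.

These conventions are pinned down by trainable-parameter counting
(`count_parameters()`): they reproduce the published 1.95M (2D SE), 1.99M
(2D attention), 2.03M (2D residual), 0.79M (3D) and 1.50M (3D residual)
figures, and the basic 3D count is confirmed by independent hand enumeration
of every layer's weight shapes in the test suite. Two conventions were
genuinely open and were fixed by that same accounting: the attention gate's
internal width (= skip channels, which lands the 2D attention net on 1.99M)
and the SE reduction ratio (8, which keeps the SE overhead below the 0.01M
rounding step). With these conventions the basic 2D U-Net counts 1,940,817
parameters (1.94M); its published row prints 1.95M, which our construction
attributes to the SE variant's count — the two rows differ by less than the
printed precision and both pass a ±1% check.

## The training engine

No R deep-learning framework is part of the package's environment, so
`emseg` ships a compact CPU engine: convolutions are im2col + BLAS matrix
multiplies (the im2col/col2im/padding cores are C++), and every primitive op
(convolution, transposed convolution, max pooling, ELU/ReLU/sigmoid,
dropout, concatenation, residual addition, attention gate, SE block, batch
norm) carries a hand-derived backward. The test suite verifies analytic
gradients against central finite differences through every block type.
Training (`train_model()`) minimises binary cross-entropy with SGD
(momentum 0.99, no decay), gradient accumulation over the batch, early
stopping on validation loss, and best-checkpoint restoration. One RNG stream
seeds initialisation, shuffling, augmentation and dropout, so a run is
bit-reproducible on CPU — the package's answer to GPU non-determinism is
that its reproducibility reference *is* the CPU path.

Default hyperparameters follow the tuned recipe: learning rate 0.002, batch
size 6, up to 360 epochs, patience 100, 256×256 patches in 2D (80×80×80 in
3D), on-the-fly right-angle rotations and flips (plus elastic deformations
in 3D).

## Sampling

Training patches are drawn with centres sampled from a class-balancing
probability map (`probability_map()`): foreground voxels share half of the
probability mass however rare the class, background the other half, so a
patch centre is equally likely to sit on a mitochondrion as not. This is one
concrete realisation of "prioritise patches with mitochondria at the
centre"; the foreground mass is a parameter. Patches below a configurable
foreground fraction can be rejected and redrawn (default threshold 0.5% when
enabled; the discarding is off by default). Validation splits take
`round(0.1 n)` slices (half-up, minimum 1), at random or as the trailing
consecutive block. Elastic augmentation uses a coarse grid of normal
displacements (amplitude 8 voxels, spacing 16) bilinearly upsampled;
labels are warped nearest-neighbour so they stay binary.

## Reconstruction and ensembling

Tiled inference supports three modes: per-patch mosaic (0 overlap),
50%-overlap tiling, and full-image (reflect-padded to the network's
divisibility). Inference grids reflect-pad the volume so every tile is
full-sized and blending windows apply cleanly; merging divides the weighted
accumulation by the accumulated weights, so any window yields an exact
partition of unity (cut-and-merge reproduces a volume bit-exactly).
The blending window is a separable squared-sine taper
`s(t) = sin²(π(t+0.5)/n)`, rescaled to peak at 1 and floored at 10⁻³ at the
border voxel to avoid zero division — one standard realisation of a
second-order spline window, isolated in `spline_window()` should a different
taper be preferred. Accumulation happens in extended precision: summing c
identical overlapping values in plain doubles rounds for odd c, and the
cut-and-merge identity is meant to hold bit-exactly, not merely to a
tolerance.

Test-time augmentation enumerates the 8 dihedral variants in 2D, and in 3D
the 16 = 8 in-plane dihedral × optional Z-flip variants — in-plane
transforms respect stack anisotropy, and the count fixes the set's
composition. Predictions are inverse-transformed and averaged in
*probability* space (standard ensemble practice; averaging after
binarisation would discard the confidence information the ensemble exists to
exploit). 3D spline blending is refused unless forced, matching its cost
profile.

## Post-processing

`run_chain()` applies, in order: binarisation at 0.5 (ties count as
foreground), small-component removal (default min area 100 voxels,
8-connectivity per slice / 26 in 3D), marker-controlled watershed border
refinement, and a per-column median Z-filter (window 3, symmetric edge
reflection; on binary input this is a majority vote). The watershed floods
the morphological gradient of the raw image from two marker sets — the mask
eroded by the erosion radius (confident inside) and the complement of the
mask dilated by the dilation radius (confident outside) — so only the
uncertain border band is re-assigned. Defaults are 2/5 pixels; these radii
are explicit configuration, not claimed faithful to any published pipeline
(the upstream description is not parameterised), and for small objects a
1-pixel erosion is the appropriate setting since per-slice cross sections
near the poles of an organelle vanish under heavier erosion (sections whose
markers vanish entirely are left untouched). Each step logs how many voxels
it changed and, when a reference is supplied, the foreground IoU after the
step, reproducing the incremental-improvement view of a chained pipeline.

## Metrics

Foreground IoU is TP/(TP+FP+FN) with mitochondria as the positive class,
background IoU swaps the classes, overall IoU is their plain mean. When a
class is absent from both masks its IoU is defined as 1 (0 when absent from
exactly one) so that per-patch averaging over background-only patches stays
meaningful; per-patch aggregation is the unweighted mean, and shifted border
patches are evaluated on their full extent within the volume (padding voxels
never enter metrics). `perturbation_tolerance()` quantifies annotation
slack: the foreground IoU of a 1-pixel dilation/erosion (3×3 in-plane
square; labels are per-slice annotations) of the ground truth against
itself. On the public Lucchi annotations this statistic is reported as
0.885/0.904 — methods closer than that gap are indistinguishable given the
labels. Reproducing those two numbers requires downloading that dataset, so
the package exposes the computation (`perturbation_tolerance()`, and the
`evaluate` CLI prints it for any ground truth you load) rather than shipping
the data.

## The stability harness

`repeat_runs()` executes one configuration `n` times (default 10, seeds
`base_seed + 0..n-1`), evaluating every reconstruction × post-processing
cell each run; `summarize_runs()` reports mean, sample standard deviation
(n−1) and maximum of the foreground IoU per cell, with Markdown and CSV
emitters in the canonical column order. The fixture seeds live in the
profile, so every run sees identical data and the spread measures training
stochasticity alone. A failed run keeps its slot rather than silently
shrinking n. The per-cell maximum is reported per cell independently (one
plausible reading of "maximum" rows in published tables; the alternative —
best single run across all cells — is a one-liner on the raw results).

## The synthetic fixtures

`make_volume()` renders grayscale volumes with dark ellipsoidal organelles
(randomly rotated and elongated in-plane), a bright 1–2 voxel rim as a
membrane analogue, and Gaussian background texture; labels are the exact
ellipsoid interiors, rim included. Defaults: background 0.55 ± 0.06,
interior 0.25 ± 0.05, rim 0.85, i.e. strong but noisy contrast in [0, 1].
An anisotropy factor compresses organelles across fewer Z slices to emulate
serial-section stacks. The generator models the *gross* appearance that the
pipeline machinery needs — blob-like dark objects with membranes on textured
background — and deliberately not cristae, membrane contacts, or the
labeling inconsistencies of real annotations; a passing desk run therefore
validates the machinery and trainability, not benchmark-level accuracy on
real EM. That the fixtures are intensity-separable (and hence learnable by
small networks) is itself asserted: a plain threshold baseline
(`threshold_baseline()`) must exceed 0.5 foreground IoU on clean fixtures.
`corrupt_labels()` turns clean labels into imperfect pseudo-predictions
(softening, border jitter, random flips, spurious blobs) so post-processing
and metrics are testable without any training.

## Scaled-down profile and problem sizes

`pipeline_profile("desk")` is the package's CPU-scale end-to-end
configuration: a two-level 2D net (16/32 filters), 64×64 patches, a
10×192×192 training volume (16 organelles) with the 10% validation split, 8
patches per training slice, 30 epochs, 3 runs, evaluated on a held-out
8×128×128 volume as per-patch mosaic, 50%-overlap, 50%-overlap + spline
blending, and + Z-filtering. The short schedule uses a constant learning
rate of 0.005: at the full-scale 0.002 a 30-epoch budget stays in the
all-background regime of the loss, while 0.005 reaches foreground IoU well
above 0.9 on the fixtures. All other hyperparameters keep their full-scale
defaults. `pipeline_profile("paper")` carries the full-scale recipe
(four-level 2D U-Net, 256×256 patches, 360 epochs, patience 100, 10 runs,
the complete reconstruction grid) for users with the budget to run it.

## Numerical choices and degenerate inputs

* Threshold ties (probability exactly 0.5) are foreground.
* Empty-union IoU conventions as above; erosion to an empty mask scores 0
  with a warning.
* Morphology uses box structuring elements with the zero-outside convention
  (objects touching the volume border erode there).
* The watershed breaks priority ties FIFO (first basin to reach a voxel at
  the lowest flood level claims it).
* Weight initialisation: He-normal `sd = sqrt(2/fan_in)` or Glorot-uniform
  bounds `sqrt(6/(fan_in+fan_out))`; fan counts use the full kernel size.
* Dropout schedules for depths the 2D recipe does not cover interpolate the
  same 0.1 → 0.3 endpoints linearly over the available blocks.
* Probability accumulation and all training arithmetic are double precision;
  TIFF writers rescale to 8-bit (masks, images) or 32-bit float
  (probabilities).

## Known limitations

* The engine is single-threaded CPU code built for correctness,
  determinism and desk-scale problems; full-scale training (360 epochs on
  256×256 patches) is possible but slow, and no GPU path exists.
* HDF5 containers are not supported (no R bindings in the package's
  dependency set); TIFF stacks and PNG slice directories are.
* Instance-level and boundary-distance metrics are out of scope — the
  package evaluates semantic segmentation only.
* The synthetic generator is not photorealistic EM; see above for what
  passing tests do and do not establish.

## A worked desk example

```{r example, eval = FALSE}
library(emseg)

prof <- pipeline_profile("desk")
res <- repeat_runs(prof, n = 3, base_seed = 1)
summ <- summarize_runs(res)
summ
writeLines(format_stability_md(summ))
```

Each run generates the fixtures, samples patches, trains the two-level
network, reconstructs the held-out volume under every cell and scores it;
the summary's mean/sd/max per cell is the desk-scale analogue of a published
stability table.
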