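---
title: "Semi-supervised 3D vessel segmentation with sparse slice annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised 3D vessel segmentation with sparse slice annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vesselssl)
```

## The problem

High-resolution 3D imaging of soft tissue — for example hierarchical
phase-contrast tomography (HiP-CT) of lung biopsies at micrometre scale —
produces volumes far too large to annotate densely. In practice a labeller
marks vessels on every k-th slice (k ≈ 5) and interpolates between, so the
resulting "ground truth" covers well under 2% of the voxels, misses entire
vessels, and labels the rest of the volume as background even where vessels
are present. Supervised segmentation trained on such masks inherits those
systematic errors. Semi-supervised learning (SSL) tries to buy back accuracy
from the abundant unlabeled data.

`vesselssl` implements two SSL training schemes around a compact 3D
convolutional encoder–decoder written from scratch (double precision,
single-threaded, deterministic), plus everything needed to exercise them end
to end: a synthetic vascular phantom generator, volume I/O and normalization,
overlapping patch planning with label-density filtering and mean-blended
stitching, annotation-aware evaluation, and a CLI.

## The backbone

The network is a plain U-style encoder–decoder: per-level channel doubling,
3×3×3 convolutions with ReLU, 2× average-pool downsampling, nearest-neighbour
upsampling, and skip concatenation, ending in a 1×1×1 convolution and a
sigmoid. Depth, base channels and input size are configurable
(`mismatch_config()`); the default used throughout the tests is depth 2 with
2–4 base channels, which trains in minutes on a single CPU core. The
convolution forward/backward kernels live in C++ (`src/conv3d.cpp`); all
gradients are hand-derived and verified against finite differences in the
test suite.

## Dual-decoder consistency ("MisMatch" scheme)

One shared encoder feeds two parallel decoders whose attention side-branches
carry *opposed effective-receptive-field (ERF) biases*:

* the **positive attention-shifting decoder** computes a sigmoid attention map
  with a dilated 3×3×3 convolution (dilation 5 by default) and multiplies it
  into the main branch — a wide ERF biases it toward *dilated* foreground;
* the **negative attention-shifting decoder** computes its attention with a
  pointwise 1×1×1 convolution, the shortest possible side path — a narrow ERF
  biases it toward *eroded* foreground.

The final prediction is the exact voxelwise mean of the two decoder
probability maps. Training combines a supervised Dice loss on that mean over
labeled patches with a mean-squared-error *consistency* loss between the two
decoder outputs over unlabeled patches, weighted by α:

L_total = Dice(p_final, y) + α · MSE(p⁺, p⁻).

Design choices where the scheme leaves room:

* supervision is applied to the merged prediction `p_final`, not per decoder;
* consistency is computed on probabilities (post-sigmoid), not logits;
* the consistency gradient flows into both decoders symmetrically (no
  stop-gradient);
* Dice smoothing ε = 1e-6 guards all-background patches.

The ERF claim is measurable: `erf_radius()` propagates the gradient of the
central output voxel back to the input, accumulates absolute gradient mass
over several random inputs (single inputs can have locally dead ReLU paths),
and summarizes it as a mass-weighted RMS radius. The positive decoder
measures a strictly larger radius than the negative one across weight seeds —
the test suite and the acceptance script both recompute this.

## Pseudo-label EM ("SegPL" scheme)

Pseudo-labelling is framed as expectation–maximization around a single-output
backbone. The **E-step** thresholds the model's probabilities on unlabeled
patches at a fixed confidence T (default 0.5; a voxel at exactly T maps to 1,
a closed tie rule the tests pin down). The **M-step** takes gradient steps on

L_total = L_L + α · L_U,

where both terms are Dice losses — L_L against the true sparse labels, L_U
against the fixed pseudo-labels. The loop iterates to a budget or until the
relative change of the exponentially smoothed total loss falls below a
tolerance. Variational learning of T is out of scope; all voxels receive
pseudo-labels (no confidence masking).

Two stability mechanisms matter in practice, and both are exposed as
configuration:

* **Warm-up** (`warmup`): pseudo-labelling only starts after a stretch of
  supervised-only steps. Pseudo-labels harvested from an untrained model are
  almost all background (or almost all foreground); training against them at
  step 1 collapses the model before the supervised signal can act. This
  follows the classical formulation of pseudo-labelling, in which the network
  first trains on the labeled data alone.
* **Periodic E-step** (`e_step_every`): pseudo-labels for the whole unlabeled
  pool are recomputed every N steps and *frozen* in between, each cached
  pseudo-label volume being co-augmented with its patch exactly like a
  labeled pair. Refreshing the pseudo-labels from every forward pass
  (`e_step_every = 1`, the fully online variant, also available) lets the
  model chase its own expanding predictions: a voxel that drifts above T is
  immediately relabelled foreground and pushed further up, a positive
  feedback that can run away to an all-foreground fixed point. Freezing the
  targets between E-steps makes each M-step optimize against a stationary
  objective, which is also the orthodox EM reading.

The unsupervised weight α additionally supports a linear ramp
(`alpha_ramp`) from 0 after the warm-up, a standard damping of
self-training feedback.

## Synthetic phantoms and what they do (not) show

No real annotated HiP-CT volumes are distributed, so the package generates
its own study material. `generate_phantom()` grows vessels as random-walk
centerline tubes (`tortuosity` scales the angular step deviation; 0 gives
straight tubes) with two intensity classes inside the vessel — a wall and a
brighter lumen — against a darker background, each sampled from a Gaussian.
The defaults (background/wall/lumen means 0.35/0.55/0.75, sd 0.12, arbitrary
units) deliberately make the class histograms overlap heavily, as observed in
real fibrotic tissue, while remaining learnable by a small network. Voxel
spacing (2.5 µm isotropic by default) is carried as opaque metadata and never
used numerically.

`sparsify_annotation()` emulates the labelling practice: keep labels on every
k-th slice (optionally thinned by a `completeness` fraction), zero the rest,
optionally refill by nearest-neighbour shape interpolation between annotated
slices (mirroring grow-from-seeds interpolation workflows, without
re-implementing them).

What the phantoms do **not** emulate: fibrosis texture, airways, intensity
inhomogeneity, annotation noise beyond simple thinning, and the sheer scale
of real scans. Passing tests on phantoms therefore demonstrates that the
training machinery behaves as specified — not that any method reaches a
particular accuracy on real tissue.

## The sparse-label benchmark

`ssl_benchmark()` is the package's end-to-end experiment. Per seed: three
phantoms (train / unlabeled / held-out test, 64³); training labels
sparsified to cadence-5 slice annotation with no interpolation and treated
as-is (unannotated voxels count as background, matching the practice of
training on sparse masks directly; a masked-loss variant restricted to
annotated slices is available in `fit_model()`); overlapping 32³ patches,
training patches filtered to ≥1 labeled voxel; 16³ random crops into a
depth-2, 2-channel backbone; 300 Adam steps at learning rate 5e-3, batch 2
labeled + 2 unlabeled. The held-out score is dense-ground-truth Dice of the
stitched, 0.5-binarized prediction — the luxury a real study lacks.

Hyperparameter choices: α = 0.1 for the consistency scheme and α = 0.1 with
warm-up (first third of the steps) plus α-ramp for the EM scheme. Larger
weights (α = 1) destabilized both schemes on these conditions — the
consistency loss then dominates the thin supervised signal and the trivial
all-agree solutions become attractors — consistent with the observation that
decreasing the unsupervised weight improves stability on sparsely labeled
vessel data. Problem sizes (64³ volumes, 300 steps, 3 seeds) were chosen so
the full benchmark runs in minutes on one CPU core; they are small, and the
resulting Dice numbers carry seed-to-seed spread of a few points.

## Numerical and convention choices

* Axis order is (z, y, x), 0-based origins, half-open windows `[o, o+s)`
  everywhere; patch origins are lexicographically ordered.
* Patch planning clamps the final window per axis to end exactly at the
  volume edge (no padding), so edge statistics are real intensities.
* Stitching averages overlapping predictions with uniform weights, making
  stitch∘extract the identity for any valid plan.
* Label-density filtering uses strict inequalities (">0" means ≥1 voxel;
  numeric levels mean strictly greater).
* `dice_score(empty, empty) = 1` by convention — all-background patches are
  routine in sparse data and should count as agreement.
* Inference binarizes at 0.5; no connectivity-aware post-processing ships.
* Normalization is per-volume (z-score or min-max), applied before patching;
  a constant volume maps to all zeros.
* The "auto" foreground-crop threshold is Otsu's method on the intensity
  histogram.
* All randomness flows through named, independently seeded RNG streams
  (weights, labeled sampling, unlabeled sampling, augmentation), so runs
  reproduce bit-for-bit on one CPU thread, resumed runs continue identically,
  and a loop that never consumes the unlabeled stream (α = 0) draws exactly
  the same labeled batches as one that does — which makes the α = 0
  reduction-to-supervised equivalence exact rather than approximate.

## Known limitations

* The backbone is intentionally small; no claim is made that it matches
  large-scale U-Net variants on real data.
* Volumes are processed in memory; streaming extraction for organ-scale
  scans is out of scope.
* Pseudo-label EM remains sensitive to its stability hyperparameters; the
  periodic E-step and warm-up defaults make the shipped benchmark stable, but
  other data regimes may need retuning.
* Checkpoints use R serialization and are not portable across architectures.
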