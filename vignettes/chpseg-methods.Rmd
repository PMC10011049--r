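---
title: "Coarse-to-fine segmentation of sparse bright brain structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine segmentation of sparse bright brain structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The choroid plexuses (ChP) are thin, veil-like, vascularized structures
inside the brain ventricles. On a T1-weighted MPRAGE they appear as faint
bright filaments floating in the dark CSF of the lateral ventricles, and
they occupy on the order of 0.1–0.3 % of the voxels of a whole-head
acquisition. Segmenting them volumetrically is the basis for using ChP
enlargement as a neuroinflammation proxy, but the extreme class imbalance
and the thin geometry defeat naive whole-volume approaches: at full
resolution a single 3D network must either be shallow (memory) or see the
target as a vanishing fraction of each batch.

`chpseg` implements a two-stage ("2-step") cascade that addresses this
directly:

1. **Coarse stage.** The whole preprocessed volume (176 × 240 × 256 at
   1 mm³) is downsampled to 72 × 96 × 104 and segmented by a 3D
   encoder–decoder. Its output is not used as a segmentation but as a
   *detector*: every low-resolution voxel with probability strictly above
   0.8 nominates a full-resolution patch location.
2. **Fine stage.** Up to 500 cubic patches of 48³ voxels, centered on the
   nominated locations (overlap allowed), are segmented at native
   resolution by a second network with the same architecture.
3. **Merge.** Patch predictions are multiplied by a separable 3D Hann
   window, accumulated into the output volume, and divided by the
   accumulated window mass, so overlapping patches blend smoothly and every
   covered voxel is a convex combination of patch predictions. The merged
   probability map is binarized at a strict 0.5.

A single-stage baseline ("1-step") — the same network applied to the whole
high-resolution volume — is included for comparison.

## Preprocessing

Volumes are reoriented to a canonical axis order (left–right, then
antero-posterior, then infero-superior; RAS codes), resampled to isotropic
spacing with output shape `round(shape × spacing_ratio)` per axis, cropped
or padded symmetrically to the target grid, and intensity-rescaled so the
0.5th percentile maps to −1 and the 99.5th to +1 with values beyond the
band clipped to the interval ends. Each step records what it did
(`PreprocessRecord`), so predictions can be mapped back to the native voxel
grid exactly (`invert_preprocess()`); masks travel through the same spatial
steps with nearest-neighbour interpolation and remain binary.

Choices the literature leaves open, fixed here once:

* Interpolation is trilinear for intensities and nearest-neighbour for
  masks, everywhere (resampling, coarse downsampling, augmentation).
* Crop/pad is centered; an odd remainder puts the extra voxel on the
  high-index side; the pad value is the pre-rescale grid minimum
  (background).
* 4D NIfTI files with a trailing singleton dimension are squeezed with a
  message; other 4D inputs are rejected.
* R's 1-based indexing is used throughout the interfaces; the coarse-to-fine
  seed mapping is computed on 0-based offsets (`round((i−1)·scale)+1`) so
  the index arithmetic is the conventional one.

## Architecture

Both stages share one architecture: a 3D U-Net-style encoder–decoder with
4 levels and 16 filters after the first convolution block (channels double
per level), modified in three ways that matter at small batch sizes and
tight memory:

* **Group normalization** (8 groups) instead of batch normalization —
  stable for batches of 1–4 volumes.
* **Leaky ReLU** (slope 0.01) instead of ReLU, avoiding dead units.
* **Parameter-free nearest-neighbour upsampling** in the decoder instead of
  learned transposed convolutions, reducing the trainable parameter count
  (`count_parameters()` vs. the transposed-convolution variant verifies the
  inequality).

Each convolution block is convolution (3³, stride 1, same padding) → group
norm → leaky activation; two blocks per level; 2× max pooling between
encoder levels; skip connections concatenate encoder features into the
decoder; a final 1×1×1 convolution and a logistic sigmoid give a
single-channel probability map. Every spatial extent the network sees must
be divisible by 2^(levels−1); the stated default shapes all are.

The final convolution bias is initialized at `qlogis(0.01)`, the logit of a
1 % foreground prior. With a sparse target, a symmetric initialization
makes early training spend its budget suppressing the background class and
can trap the coarse stage below the 0.8 seeding threshold for its entire
(short) schedule; the prior-logit initialization — standard practice for
sparse detection heads — removes that failure mode without touching the
loss or thresholds.

All computation runs in R's native 64-bit floating point. The convolution
forward/backward passes are im2col + BLAS GEMM kernels (C++/Armadillo);
the backward data gradient is computed as a forward convolution with the
spatially flipped, channel-transposed kernel, which is exact for odd
kernels with symmetric zero padding.

## Loss

For probability grid $x$ and binary target $y$:

$$\mathrm{Dice}(x, y) = \frac{2\sum_i \min(x_i, y_i)}{\sum_i x_i + \sum_i y_i},
\qquad \mathrm{DL} = 1 - \mathrm{Dice}, \qquad \mathrm{Loss} = \mathrm{DL} + \mathrm{BCE}.$$

The min formulation coincides with the classic overlap Dice on binary
inputs (property-tested against a counting oracle). Two empty grids give
Dice 1 (loss 0) by convention. BCE is the voxel mean with predictions
clamped to `[1e-7, 1 − 1e-7]`.

The cascade loss is conditional on the number $N$ of patch locations the
coarse stage produced:

$$\mathrm{Loss}_{2\text{-step}} =
\begin{cases} \mathrm{Loss}_{step1} & N = 0\\
\mathrm{Loss}_{step1} + \mathrm{Loss}_{step2} & N > 0 \end{cases}$$

with the fine-stage term averaged over the patch batch (per-patch DL + BCE;
the reduction across patches is not dictated by the formulation, the mean
is the scale-stable choice). When $N = 0$ the fine stage receives no
update — the `N = 0` branch is bit-exact, not approximate.

## Training

Adam with initial learning rate 1e-3; the rate is halved whenever the
validation loss changes by less than 1e-3 between two consecutive epochs
(no patience window — the consecutive-epoch reading is deliberate and
tested: two plateau events give exactly 1e-3 → 5e-4 → 2.5e-4). The
validation quantity for the schedule is the full cascade loss. Coarse-stage
targets are nearest-neighbour downsampled masks (binary by construction,
same voxel-center mapping as the image downsampling). During training,
patch seeds come from the *current* coarse output under the strict 0.8
rule; patch targets are ground-truth crops at the sampled locations; the
defaults train with 4 low-resolution volumes per update and up to 16
patches per volume (a 64-patch fine-stage batch), 200 epochs for the
cascade and 100 for the single-stage baseline.

## Augmentation

Nine transforms, each triggered by an independent Bernoulli draw, composed
spatial → k-space → intensity (the order of physical acquisition); spatial
transforms apply the identical geometric map to the mask with
nearest-neighbour interpolation:

| transform | p | bounds |
|---|---|---|
| left–right flip | 0.5 | — |
| affine | 0.3 | scale 1 ± 0.3, rotations ± 15° |
| anisotropy | 0.3 | one random axis, factor ≤ 2, down- then upsampled |
| k-space motion | 0.3 | ≤ 2 movements, ± 15°, ± 15 mm |
| k-space ghosting | 0.3 | every 2nd frequency plane, random axis |
| k-space spike | 0.3 | 1 spike |
| bias field | 0.3 | order-3 polynomial, coefficients ± 0.5 |
| Gaussian noise | 0.3 | mean 0, sd 1 |
| gamma contrast | 0.3 | \|log γ\| ≤ 0.3 |

Magnitudes without a stated distribution (ghost modulation depth, spike
amplitude, bias coefficients) are drawn uniformly within their bounds.
Motion is simulated by assembling the frequency domain from contiguous
segments of rigidly displaced copies; ghosting attenuates every n-th
frequency plane (DC excluded); a spike adds one high-magnitude complex
point (its residual is verified in the tests to be a pure plane wave
against a direct cosine evaluation). Elastic deformation is deliberately
not part of the battery. Zero-magnitude settings of every k-space and
intensity transform are identities within 1e-5, and trigger frequencies are
property-tested over 1000 seeded draws.

## Evaluation

Per subject: Dice, recall ($|X\cap Y|/|Y|$), precision ($|X\cap Y|/|X|$),
signed volume error rate $\mathrm{VER} = (|X|-|Y|)/|Y|$ and its absolute
value. Subjects with an empty reference raise an error rather than produce
0/0 scores; `cohort_summary(skip_undefined = TRUE)` drops and counts them.
Cohort level: mean ± standard error of the mean (sample SD / √n) per
metric, plus Pearson's r between predicted and reference volumes (voxel
counts; identical to mm³ at unit spacing).

## The phantom generator

Real T1 volumes cannot ship with the package, so every pipeline property is
exercised on synthetic phantoms built to carry exactly the features that
make the task hard:

* an ellipsoidal "brain" (intensity 0.6) over dark background (0.05);
* two dark ellipsoidal cavities (0.15) placed left and right of the
  midline — the lateral-ventricle stand-ins;
* inside each cavity a thin bright tube (1.0) grown by a persistent random
  walk, dilated to a 1-voxel radius and clipped to the cavity — the
  ChP stand-in, with a target volume fraction defaulting to 0.2 % of the
  volume (cohorts draw fractions uniformly from 0.1–0.3 % so ground-truth
  volumes vary, which the volume-correlation statistics need);
* Gaussian smoothing (0.8 mm) as partial-volume blur, then additive
  Gaussian noise (sd 0.05, strong contrast-to-noise as in an MPRAGE).

The ground truth is the pre-smoothing tube. The contrast ordering
(cavity < brain < target), the sparsity and the thin curvilinear geometry
are the properties the cascade exploits; the phantom does **not** emulate
cortical folding, bias fields, multi-tissue intensity distributions, or
inter-subject anatomy. Tests passing on phantoms therefore demonstrate the
*mechanics* of the pipeline (seeding, merging, loss behaviour,
learnability of a sparse bright-in-dark target), not clinical performance.

## Desk-scale verification runs

Two scales are exercised in the test suite and the acceptance script,
chosen as the package's own desk-scale study conditions:

* **Oracle fidelity.** With ground-truth oracles substituted for both
  networks, the end-to-end two-step pipeline on ten 96³ phantoms must
  exceed Dice 0.95 — everything lost is interpolation and merge error.
* **Parameter recovery.** A reduced cascade (3 levels, 8 base filters,
  24³ coarse grid, 16³ patches) is trained from scratch for 30 epochs on
  12 phantoms of 96³ voxels and evaluated on 4 held-out phantoms, for
  three seeds; mean validation Dice ≥ 0.6 is required for at least two of
  the three. Training uses one volume per update and 4 patches per volume
  (group normalization is batch-size robust, and more updates per epoch
  suit the 30-epoch budget; the full-scale 4/16/64 batch shape was a
  GPU-memory ceiling, not a tuned value). A run takes a few minutes on one
  CPU core. This is a stand-in demonstrating that the cascade carries
  learnable signal at desk scale — not a reproduction of cohort-level
  accuracy on real MRI.

## Numerical choices and degenerate inputs

* Hann window sampled at interior points,
  $w_i = 0.5(1 - \cos(2\pi (i+1)/(n+1)))$, so edge weights are strictly
  positive and the divide-by-weight merge is defined on every covered
  voxel (the classic endpoints-zero Hann would leave isolated-patch edges
  0/0).
* Strict inequalities at both thresholds (seeding 0.8, binarization 0.5);
  a voxel exactly at threshold is excluded.
* No-seed inference returns an all-zero map and empty mask with a warning
  (the conditional loss defines the N = 0 case only for training; inventing
  an upsampled coarse output at inference would silently change the
  method).
* Constant-intensity volumes make percentile rescaling degenerate and
  raise an error naming the cause.
* BCE clamp 1e-7; group-norm epsilon 1e-5; partition-of-unity merge error
  tolerance 1e-5.
* Candidate subsampling beyond the 500-patch cap is uniform without
  replacement; with fewer candidates than the cap each is used exactly
  once (no duplication to fill a quota).
* The fine stage receives image patches only (no coarse-probability input
  channel).

## Known limitations

* The phantom's simplicity means desk-scale Dice values are far above what
  heterogeneous clinical data yields; they validate plumbing and
  learnability, not accuracy claims.
* Bias-field correction (N4) is assumed done upstream and is out of scope,
  as is registration to any template.
* Training is single-device CPU R; the implementation favours correctness
  and reproducibility (bit-reproducible under a seed) over throughput, and
  full-scale (176 × 240 × 256, 200-epoch) training is out of desk reach.
* Inter-method statistics on real cohorts (mixed-effects models, paired
  tests) are not implemented; the evaluation module stops at per-subject
  scores, cohort mean ± SEM and volume correlation.
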