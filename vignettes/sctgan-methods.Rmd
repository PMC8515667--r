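---
title: "Attention-guided adversarial CBCT-to-CT synthesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided adversarial CBCT-to-CT synthesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sctgan)
```

## The problem

Cone-beam CT (CBCT) acquired on the treatment machine is the workhorse of
image-guided radiotherapy, but scatter, under-sampling and patient motion
distort its Hounsfield units: lungs appear far too dark, soft tissue carries
cupping and shading bias, and streaks cross the axial planes. Distorted HU
make CBCT unusable for dose recalculation in adaptive radiotherapy. `sctgan`
learns a mapping from CBCT to a *synthetic CT* (sCT) whose HU values behave
like a planning CT, using **unpaired** adversarial training — important
because thoracic CBCT/CT pairs can never be aligned perfectly under free
breathing, and voxel-wise supervised training bakes those misalignments into
the network.

## The attention-guided generator

A translation generator G maps a normalized axial slice (values in [-1, 1]
after clipping to [-1000, 1500] HU) to its counterpart in the other domain.
Its encoder (7×7 stem, two stride-2 3×3 convolutions, residual blocks at the
bottleneck width) is shared by two decoder branches:

* a **content branch** producing n − 1 candidate images
  C_1 … C_{n−1} (tanh-bounded to [-1, 1]), and
* an **attention branch** producing n masks through a per-pixel channel
  softmax, so the masks are non-negative and sum to one at every pixel.

One designated mask is the *background* mask A^b; the rest are foreground
masks A^f_k. The output is the convex composition

    out = sum_k C_k * A^f_k + input * A^b .

Because the attention channels form a simplex and each term is bounded, the
output can never leave [-1, 1]; where the background mask saturates to 1 the
input passes through bit-exactly. The intuition: artifacts occupy localized
regions (lungs, chest wall), and the attention lets the generator rewrite
exactly those regions while *copying* anatomy it should not touch — this is
what preserves structures that plain encoder–decoder translators destroy.
With n = 10 (the default) there are 9 content channels; the baseline
`cyclegan` mode disables the attention branch (the generator emits a single
tanh image), which isolates the attention mechanism as the only difference
between the two unpaired modes.

The discriminators are patch-based (pix2pix style): a fully convolutional
stack of 4×4 convolutions scores overlapping receptive-field patches, and
the mean patch score judges the image. Per the published description, the
mean is taken *before* the least-squares penalty; the common alternative
(penalty per patch, then mean) is available via `reduce = "patch"`.

## Objectives

Training couples two generators (CBCT→CT and CT→CBCT) and two
discriminators through three loss groups, all implemented in
`lsganDLoss()`, `lsganGLoss()`, `l1CycleLoss()`, `l1IdentityLoss()` and
combined by `totalLoss()`:

* **Least-squares adversarial**: D minimizes (D(real) − 1)² + D(fake)²,
  G minimizes (D(fake) − 1)², each halved and averaged over the batch.
* **Cycle consistency** (weight 10): |G_B(G_A(x)) − x|, pixel mean — the
  constraint that makes unpaired training well-posed.
* **Identity** (weight 5): |G_A(y) − y| for y already in the target domain,
  which anchors the HU scale.

The `pix2pix` baseline trains a single generator on *paired* slices with the
adversarial term plus a strong L1 term (weight 100). It keeps the
least-squares adversarial form of the other modes so a single discriminator
code path serves all three; this is a deliberate deviation from the
original cross-entropy conditional GAN and is recorded here.

L1 reductions use the pixel *mean*, not the sum, so loss values are
independent of the slice resolution.

## Training regimen and numerical choices

Defaults mirror the published regimen: Adam (β₁ = 0.5, β₂ = 0.999), initial
learning rate 1e-4 held for the first half of training and then decayed
linearly to exactly zero, batch size 1, slice pools reshuffled every epoch
(independently per domain; jointly in paired mode). One epoch visits
max(pool sizes) iterations with the smaller pool wrapping. Per iteration the
generators are updated jointly first, then each discriminator on a
(real, detached fake) pair; an optional historical fake buffer (off by
default, `fakeBuffer`) reproduces the 50-image pool some implementations
use.

Numerical choices worth knowing:

* **Weight init** is seeded N(0, 0.02²); instance-norm gain 1, bias 0.
* **Identity-friendly attention init**: the background attention logit gets
  a +3 bias at initialization (`backgroundBias`), so a fresh generator
  starts near the identity map (background weight ≈ 0.7 rather than 1/n).
  With a neutral softmax init the early training budget is spent
  rediscovering the input image through the cycle/identity losses; starting
  near the identity spends it on learning actual corrections. The objective
  is unchanged, and `backgroundBias = 0` restores the neutral init.
* **Instance normalization** uses ε = 1e-5; the channel softmax subtracts
  the per-pixel maximum, so arbitrarily large logits cannot overflow.
* All gradients are hand-derived (the conv/transposed-conv kernels are
  im2col/col2im + BLAS); the test suite verifies every layer and the whole
  generator against central finite differences.
* Reflection padding is used for the 7×7 stem, the residual blocks and the
  content head; zero padding elsewhere. The padding adjoints are exact,
  which the gradient checks confirm.

## The digital thorax phantom

Real patients and the commercial thorax phantom behind the published tables
are not distributable, so the package ships a parametric stand-in
(`generatePhantom()`): an elliptical body of soft tissue with two lung
ellipses, a spinal column and eight rib cross-sections, voxelized on a
configurable grid with per-tissue Gaussian HU texture. Tissue means default
to CT measurements of a thorax phantom — lung −755, bone 716.2, soft tissue
−27.5 HU — with SDs (45/80/30 HU) chosen as plausible voxel-level texture.
Anatomy jitters by ±5% between volumes to emulate inter-patient variation.

`simulateCBCT()` adds the CBCT degradations reported for low-dose thoracic
scans as independent, additive HU fields: a uniform lung depression, a
raised-cosine radial cupping field (the classic scatter signature), angular
streaks of alternating sign, a one-sided directional shading field, and
white Gaussian noise, followed by the [-1000, 1500] clip. The lung shift
default (−83 HU) is calibrated so the *composite* default artifact brings
the phantom lung mean to ≈ −900 HU, the level measured on CBCT of the same
phantom; soft tissue drops by ≈ 80 HU, reproducing the patient-cohort
direction. Each component draws from its own derived seed, so switching one
off never changes the others.

What the phantom does **not** emulate: physics-based projection and
reconstruction (no Monte Carlo, no FDK), respiratory motion, correlated
noise textures, or anatomical detail beyond the four tissue classes.
Passing the end-to-end benchmark therefore demonstrates that the training
machinery can learn to invert a *systematic, spatially structured* HU
distortion from unpaired data — not that the defaults reach clinical-grade
image quality on real patients.

## The scaled benchmark

The published experiments trained for hundreds of GPU-hours; the package's
standard benchmark is scaled to run on one CPU core in minutes, and those
sizes are stated here as the package's reference configuration: 10 phantom
volumes of 64 × 64 × 6 voxels (8 training / 2 held-out), generator channels
(6, 12, 24) with 3 residual blocks and n = 10 masks, discriminator base
width 8 with 2 stride-2 layers, 20 epochs with decay from epoch 10. Under
fixed seeds the held-out sCT must beat the input CBCT on both MAE and SSIM
— the direction the published tables report. The acceptance script
(`scripts/acceptance.R`) reruns exactly this benchmark.

## Image-quality metrics

`maeHU()`, `ssimHU()`, `psnrHU()` operate on whole clipped volumes by
default (a mask argument exists because it is genuinely ambiguous whether
air outside the patient should count). SSIM is computed slice-wise on axial
planes with an 11×11 Gaussian window (σ = 1.5), K₁ = 0.01, K₂ = 0.03, over
the valid interior, then averaged; PSNR and SSIM use a data range of
2500 HU (the clipped dynamic range) and every report records that choice.
Cohort tables report mean ± SD *across volumes*. `pairedWilcoxon()` wraps
the standard signed-rank test (exact for small untied samples, normal
approximation with corrections otherwise) at the conventional 0.05 level.

## 3D gamma analysis

`gammaIndexMap()` implements the standard combined dose-difference /
distance-to-agreement index: for each reference voxel the minimum over
candidate positions of sqrt(d²/dta² + ΔD²/δ²), with δ a percentage of the
global maximum reference dose by default (local normalization is an
option). Candidates form a regular world-space grid (default step dta/10,
radius 3·dta) visited in order of increasing distance, so the spatial term
provides an exact early-exit bound and the optimized search returns exactly
the exhaustive-search answer over the same candidate set; the evaluated
dose is trilinearly interpolated in world coordinates, which also handles
mismatched grid geometries without a separate resampling pass. The
low-dose threshold (default 10% of the maximum) excludes irrelevant voxels
from the passing rate, and `gammaPassingRates()` evaluates several criteria
on one shared candidate grid, which makes the 1 mm/1% → 2 mm/2% → 3 mm/3%
passing rates exactly nested. Tests compare the search against a
brute-force oracle on coarser candidate grids (step dta/3) purely to keep
the oracle tractable.

Dose *calculation* is out of scope: the module consumes dose grids (NIfTI,
cGy) produced elsewhere, and `synthesizeDose()` provides smooth analytic
test fields.

## Known limitations

* NIfTI is the only volume format; DICOM series must be converted first.
* Volumes are assumed axis-aligned; oblique direction cosines are rejected
  at load.
* Training is CPU-bound and single-threaded beyond BLAS; the full 256×256,
  (64, 128, 256)-channel configuration is faithful but slow — use it for
  real experiments, not for the test bench.
* The identity and cycle losses apply the full attention composition (the
  generator as published); whether the original work squashed content masks
  differently is unknowable from the text, and the bounded content head is
  required by the output-boundedness contract.
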