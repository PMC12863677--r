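---
title: "Related 3D Pooling for brain-tumor segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Related 3D Pooling for brain-tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RelPoolSeg)
```

## The problem and the model

Gliomas are delineated on multi-modal MRI (native T1, post-contrast T1, T2,
T2-FLAIR) into three clinically reported, nested regions: the enhancing
tumor (ET), the tumor core (TC = ET plus the necrotic/non-enhancing core),
and the whole tumor (WT = TC plus peritumoral edema). In the BraTS label
convention these derive from an integer volume over {0, 1, 2, 4}:
ET = label 4, TC = labels {1, 4}, WT = labels {1, 2, 4}.

RelPoolSeg segments these regions with an encoder–decoder 3D U-Net that is
conventional in every respect but one: its down-sampling stages use
*Related 3D Pooling*. Each non-overlapping 2×2×2 window, flattened in
(depth, height, width) raster order, is multiplied position-wise by a fixed
non-negative weight vector

$$q = (0.03,\; 0.05,\; 0.07,\; 0.10,\; 0.13,\; 0.151,\; 0.214,\; 0.255),
\qquad \textstyle\sum_i q_i = 1,$$

and summed to one output voxel, $y = \sum_i q_i\,x_i$. Because the weights
sum to one, the operator preserves constant inputs, commutes with affine
intensity changes, and is linear with $\partial y/\partial x_i = q_i$ — a
parameter-free, fully differentiable layer. In contrast to max pooling,
every voxel of the window contributes, so local intensity relationships
survive down-sampling. Max pooling remains available as a drop-in baseline
(`poolKind = "max"`), and the two builds have identical parameter counts.

Three modelling decisions deserve explicit statement:

* **Weight-to-position mapping.** The window voxels are deliberately *not*
  sorted before weighting (sorting would make the operator a rank filter).
  We fix the mapping as raster order, `weights[1]` ↔ offset (0,0,0) through
  `weights[8]` ↔ (1,1,1). Any fixed mapping yields a valid operator; fixing
  one makes the layer deterministic and testable.
* **The weights are constants, not trainable parameters.** They were tuned
  empirically upstream of this package; learning them (e.g. as a Choquet-
  type fuzzy integral) is out of scope. They are overridable through
  `PoolingSpec`.
* **"Fuzzy measure" vocabulary.** The coefficients are sometimes described
  as fuzzy-measure exponents; the computation itself is a plain
  multiply-and-sum with normalized coefficients, and that is what we
  implement and document.

## Network architecture

The default `NetworkConfig()` is: 4 input channels; three encoder stages of
two 3×3×3 convolutions + group normalization + ReLU with filter widths
32/64/128, each followed by the configured pooling; two bottleneck blocks
at width 256; a decoder mirroring the encoder with kernel-3, stride-2
transposed convolutions (realized as zero-stuffing onto the doubled grid
followed by a same-convolution, which enforces exact ×2 up-sampling) and
concatenation skips; and a 1×1×1 convolution with sigmoid producing three
per-voxel probability maps (ET, TC, WT). Weights use He-style normal
initialization, the natural choice for ReLU networks.

Open details we fixed as package defaults: the filter schedule
(32/64/128/256, halving through the decoder) and the group-normalization
group count (8) are defaults, not published values; both are exposed in
`NetworkConfig`. Group normalization is used because training runs at batch
size 1, where batch statistics are undefined.

Three pooling stages mean spatial extents must be divisible by
$2^3 = 8$; inference therefore zero-pads to the next multiple of 8 and the
network rejects indivisible inputs instead of silently padding, so that
shape bugs surface at the boundary where they are introduced.

The network is implemented natively in R. Convolutions are computed as 27
BLAS matrix products (one per kernel offset), which keeps memory at the
scale of the activations; backward passes are hand-derived and verified
against central finite differences across every layer type in the test
suite.

## The two training pipelines

Two pipelines share the architecture and optimizer but differ in intensity
normalization and augmentation, providing complementary members for the
final ensemble:

| | Pipeline A | Pipeline B |
|---|---|---|
| normalization | min–max to [0,1] between the 1st/99th percentiles of non-zero voxels | z-score of non-zero voxels |
| channel rescale ×U(0.9, 1.1) | p = 0.7 | p = 0.2 |
| channel offset +U(−0.1, 0.1) | — | p = 1 |
| Gaussian noise σ = 0.1 | p = 1 | p = 1 |
| channel dropping | p = 0.16 | — |
| per-axis flip | p = 0.8 | p = 0.5 |

Conventions we fixed where a choice had to be made: percentiles use the
linear-interpolation (type 7) definition; min–max *clips* to the percentile
range before rescaling, the only reading that guarantees all values land in
it; z-scoring uses the population (divide-by-n) standard deviation, whose
difference from the sample version is negligible at brain voxel counts;
exact-zero background voxels are never touched by either normalization;
the brain bounding box is computed on the union of non-zero support across
all four channels. Degenerate inputs (all-zero channels, zero spread) pass
through unchanged or map to zero, with a warning rather than an error, so
a single malformed channel does not abort a training run.

For augmentation, the noise application probability is not separately
specified anywhere, so we default it to 1 in both pipelines and expose it;
rescale/offset factors are drawn once per channel; the flip probability is
interpreted per axis; and the application order is fixed as rescale,
offset, noise, channel drop, flips. Only flips touch the labels, and the
test suite checks image/label alignment with a coordinate-encoded volume.

## Loss, optimization and model selection

Training minimizes the squared-denominator soft Dice loss on the three
nested region channels directly (rather than on the raw label classes,
which aligns the loss with how results are evaluated):

$$\mathcal{L} = 1 - \frac1N \sum_{n=1}^{N}
\frac{2\sum S_n R_n + \epsilon}{\sum S_n^2 + \sum R_n^2 + \epsilon},
\qquad \epsilon = 1 .$$

The factor 2 makes perfect overlap reach loss 0; `factor2 = FALSE` provides
the plain-ratio variant (whose perfect-overlap plateau is 1/2) for
completeness. The smoothing term $\epsilon$ stabilizes empty regions: an
empty prediction against an empty reference contributes a perfect term.

Optimization is Adam at a constant learning rate of 1e-4, batch size 1,
300 epochs, with one random 128³ patch per case per epoch (the
patches-per-epoch count is a package default; it is configurable).
Validation during training uses padded full-volume inference, not patches,
matching how the model is deployed. Checkpoints are written every epoch —
snapshot ensembles select non-contiguous epochs, so late checkpoints cannot
be discarded — and the epoch with the lowest validation loss is tagged as
best. Five-fold cross-validation splits are deterministic given a seed,
with fold sizes differing by at most one. Gradient clipping is off by
default. A non-finite loss aborts with a diagnostic rather than training
through NaNs.

## Inference, ensembling and label reconstruction

`predictCase()` applies the pipeline's normalization, crops to the brain
bounding box, pads to multiples of 8, runs one forward pass, removes the
padding and restores probabilities onto the original grid (zero outside
the brain). Snapshot ensembling is voxelwise arithmetic averaging of
probability maps — order-invariant and idempotent — across any set of
checkpoints, typically several epochs from each pipeline's training run;
the checkpoint epochs are passed explicitly rather than inferred.

Thresholding uses $p \ge 0.5$ (ties count as positive; the tie rule is a
package convention). Because the three sigmoid channels are predicted
independently, nothing forces ET ⊆ TC ⊆ WT, so `binarize()` enforces
nesting by union toward the larger region (TC := TC ∪ ET, WT := WT ∪ TC)
before `reconstructLabels()` applies the label algebra: label 4 on ET,
label 1 on TC − ET, label 2 on WT − TC. The algebra is exactly invertible,
and the test suite checks both round-trip directions on random inputs.

## Evaluation metrics

Per region: Dice $= 2TP/(2TP+FP+FN)$, sensitivity $TP/(TP+FN)$,
specificity $TN/(TN+FP)$, and HD95 — the maximum over both directions of
the 95th-percentile Euclidean distance (in mm, respecting voxel spacing)
from each boundary voxel of one mask to the nearest boundary voxel of the
other. Conventions: boundaries are the mask minus its 6-connected erosion;
the percentile is linear-interpolation; empty prediction *and* reference
give Dice 1 (perfect-agreement convention); sensitivity/specificity are 1
when the corresponding reference class is absent; HD95 with an empty mask
returns NaN by default, or a configurable penalty (e.g. 373.13) in
benchmark-compatibility mode, since no universal convention exists.

## The phantom generator

`generatePhantom()` builds a brain-shaped ellipsoid of non-zero intensity
on an exactly-zero background, containing strictly nested tumor ellipsoids
labelled edema (2), NCR/NET (1) and enhancing core (4). Each modality gets
its tissue mean from a 4×4 contrast table — enhancing tumor brightest in
post-contrast T1, edema brightest in FLAIR, qualitatively like real
contrast — plus Gaussian noise, floored at a small positive value inside
the brain so the non-zero support stays exactly the brain ellipsoid.
`generateDataset()` writes BraTS-layout case directories with jittered
geometry and a JSON manifest that regenerates every case bit-identically.

What the phantoms emulate: the file layout, label conventions, nested
geometry, modality-dependent contrast, zero background and additive noise
— enough to exercise normalization, cropping, augmentation, the network,
the label algebra and the metrics end to end with known ground truth.
What they deliberately do not emulate: MRI physics (bias fields, Rician
noise, partial-volume effects), lesion-shape irregularity, multi-focal
disease, or inter-site intensity heterogeneity. Passing tests on phantoms
therefore demonstrates implementation correctness, not clinical
performance; results on real data depend on training at full scale on real
cases.

## Problem sizes used in the tests

The test and acceptance suites run the complete pipeline at reduced scale,
chosen so a correct implementation passes comfortably on one CPU: the
smoke configuration (`smokeConfig()`) uses a 4/8/16/32-filter network
(group count 4), 8³ patches, learning rate 1e-2, four patches per case per
epoch and 30 epochs on the two noiseless 8³ phantoms of
`smokePhantomDataset()`. The raised learning rate and patch count relative
to the full-scale defaults compensate for the short run; with them the
network memorizes both phantoms (train Dice WT ≈ 1, loss ≈ 1e-3) with
either pooling kind. Full-resolution behaviour is covered separately by a
128³ forward-shape check with a narrow filter schedule. One implementation
detail matters for small volumes and is enforced in code: training-patch
padding and inference padding use the same symmetric-as-possible
convention, so patches and padded full volumes sit on the same voxel grid
— the network is not translation invariant, and a one-voxel inconsistency
measurably degrades small-volume accuracy.

## Known limitations

* The native R network is practical at test scale and for full-volume
  inference, but training at 128³ for 300 epochs is far slower than a GPU
  framework; the package's training harness is designed for methodological
  correctness and small-scale studies, not large-scale benchmark training.
* Pooling supports non-overlapping windows only (stride ≥ window);
  overlapping variants and 2D pooling are out of scope.
* No test-time augmentation, connected-component filtering, or per-region
  model selection; ensembling is plain probability averaging.
* Bias-field correction, registration and skull stripping are assumed done
  upstream, as in the BraTS distribution.
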