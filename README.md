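# RelPoolSeg

Volumetric segmentation of glioma sub-regions from multi-modal MRI (T1,
post-contrast T1, T2, T2-FLAIR) with a 3D U-Net whose down-sampling stages
use **Related 3D Pooling** instead of max pooling. The package targets the
BraTS conventions: integer labels {0, 1, 2, 4} (background, NCR/NET, edema,
enhancing tumor) and the three nested evaluation regions

- **ET** (enhancing tumor) = label 4,
- **TC** (tumor core) = labels {1, 4},
- **WT** (whole tumor) = labels {1, 2, 4}.

## The core operator

Max pooling keeps only the largest voxel of each down-sampling window and
discards the relationships between neighbouring voxels. Related 3D Pooling
replaces it with a fixed weighted aggregation: each non-overlapping
2×2×2 window, flattened in (depth, height, width) raster order, is
multiplied position-wise by a non-negative weight vector

```
q = (0.03, 0.05, 0.07, 0.10, 0.13, 0.151, 0.214, 0.255),   Σ q_i = 1,
```

and summed to a single output voxel:

```
y(o) = Σ_{i=1..8} q_i · x(window_i(o)).
```

Because Σq = 1 the operator preserves constants, is affine-equivariant, and
is linear with ∂y/∂x_i = q_i, so it drops into the network as a
parameter-free differentiable layer. Every voxel of the window contributes
to the output, preserving local structure that max pooling throws away.

Around the operator the package provides the full method:

- **Two training pipelines.** Pipeline A: per-channel min–max scaling to
  [0, 1] between the 1st and 99th percentiles of the non-zero voxels;
  augmentation with channel rescaling (p = 0.7), Gaussian noise (σ = 0.1),
  channel dropping (p = 0.16), per-axis flips (p = 0.8). Pipeline B:
  per-channel z-scoring of non-zero voxels; rescaling (p = 0.2), intensity
  offsets in (−0.1, 0.1), noise, flips (p = 0.5).
- **The network.** Encoder–decoder with two 3×3×3 convolutions + group
  normalization + ReLU per block, three pooling stages (related or max),
  two bottleneck blocks, transposed-convolution up-sampling with
  concatenation skips, and a 1×1×1 sigmoid head emitting ET/TC/WT
  probability maps. Implemented natively in R on BLAS matrix products,
  with hand-derived backward passes verified against finite differences.
- **Optimization.** Soft Dice loss (squared denominator, ε = 1) on the
  nested regions; Adam at a constant 1e-4, batch size 1, 300 epochs,
  five-fold cross-validation; per-epoch checkpoints for snapshot
  ensembling.
- **Inference.** Normalize → crop to the brain bounding box → zero-pad to
  multiples of 8 → forward pass → restore to the input grid; average the
  probability maps of selected snapshot checkpoints; threshold at 0.5 with
  nesting enforcement; reconstruct labels (NCR/NET = TC − ET,
  edema = WT − TC).
- **Metrics.** Dice = 2TP/(2TP+FP+FN), sensitivity, specificity, and the
  95th-percentile Hausdorff surface distance in mm.
- **Phantoms.** A synthetic generator of BraTS-layout cases (nested tumor
  ellipsoids inside a brain ellipsoid, modality-dependent contrast,
  Gaussian noise) so everything is testable without any dataset download.

## Worked example

```r
library(RelPoolSeg)

# the pooling operator on one window holding 1..8 in raster order
x <- array(0, c(1, 2, 2, 2))
k <- 0; for (d in 1:2) for (h in 1:2) for (w in 1:2) { k <- k + 1; x[1, d, h, w] <- k }
relatedPool3d(x)   # 5.834  = 1*0.03 + 2*0.05 + ... + 8*0.255
maxPool3d(x)       # 8

# train the smoke configuration on two noiseless phantoms
dataDir <- file.path(tempdir(), "phantoms")
smokePhantomDataset(dataDir)
fit <- trainPipeline(smokeConfig("related"), dataDir, file.path(tempdir(), "run"))
tail(fit$log[, c("epoch", "train_loss", "val_loss", "dice_wt")], 3)
#  epoch  train_loss    val_loss dice_wt
#     28 0.001919184 0.001378334       1
#     29 0.001789973 0.001288036       1
#     30 0.001674838 0.001206840       1

# snapshot ensemble -> nested masks -> BraTS labels -> evaluation
snaps <- selectSnapshots(fit$outputDir, 27:30)
case  <- readCase(file.path(dataDir, "phantom_001"))
maps  <- lapply(snaps, function(p) {
  ck <- loadCheckpoint(p)
  predictCase(ck$network, case$image, ck$pipeline)
})
pred <- reconstructLabels(binarize(ensembleAverage(maps)), spacing(case$image))
evaluateSegmentation(labelArray(pred), labelArray(case$labels))
#  region dice sensitivity specificity hd95_mm
#      ET    1           1           1       0
#      TC    1           1           1       0
#      WT    1           1           1       0
```

The training log shows the soft Dice loss falling to ~1e-3 as the tiny
network memorizes the two phantoms, and the ensembled prediction
reconstructs the ground-truth label map exactly (Dice 1, HD95 0 mm for all
three regions).

A thin command-line front end over the same functions ships in
`inst/scripts/relpoolseg.R` (`phantoms`, `train`, `predict`, `evaluate`,
`ensemble` subcommands).

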