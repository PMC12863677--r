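## Pipeline configurations. Pipeline A: min-max percentile normalization,
## channel dropping, frequent flips. Pipeline B: z-score normalization,
## intensity offsets, rarer flips. Both share the network, Adam with a
## constant learning rate of 1e-4, batch size 1, 300 epochs and five-fold
## cross-validation.

#' Construct a pipeline configuration
#'
#' @param id "A" or "B"; fixes the normalization mode and augmentation
#'   preset (see [pipelinePolicy()]).
#' @param poolKind "related" or "max" pooling in the network.
#' @param network a [NetworkConfig]; its `poolKind`/`poolSpec` are set from
#'   `poolKind`/`poolSpec` here.
#' @param poolSpec a [PoolingSpec].
#' @param epochs,batchSize,learningRate,folds the optimization recipe
#'   (defaults 300, 1, 1e-4, 5).
#' @param patchSize training patch extent (default 128^3).
#' @param patchesPerCase random patches per case per epoch (default 1).
#' @param seed integer RNG seed.
#' @return a [PipelineConfig].
#' @export
pipelineConfig <- function(id = c("A", "B"), poolKind = "related",
                           network = NetworkConfig(),
                           poolSpec = PoolingSpec(),
                           epochs = 300L, batchSize = 1L,
                           learningRate = 1e-4, folds = 5L,
                           patchSize = c(128L, 128L, 128L),
                           patchesPerCase = 1L, seed = 1L) {
  id <- match.arg(id)
  network@poolKind <- poolKind
  network@poolSpec <- poolSpec
  validObject(network)
  new("PipelineConfig", id = id,
      normalization = if (id == "A") "minmax" else "zscore",
      augmentation = pipelinePolicy(id), network = network,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = learningRate, optimizer = "adam",
      folds = as.integer(folds), patchSize = as.integer(patchSize),
      patchesPerCase = as.integer(patchesPerCase), seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Understands the shipped presets (`pipeline_a.yaml`, `pipeline_b.yaml`
#' under `inst/extdata`) and any file with the same keys: `pipeline`,
#' `normalization.mode`, `augmentation.*`, `network.*` (including
#' `network.pooling.kind/weights/window/stride`) and `training.*`. Missing
#' keys fall back to the pipeline defaults.
#'
#' @param path YAML file path.
#' @return a [PipelineConfig].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  id <- toupper(y$pipeline %||% "A")
  pool <- y$network$pooling %||% list()
  spec <- PoolingSpec(
    window = unlist(pool$window %||% c(2L, 2L, 2L)),
    stride = pool$stride %||% 2L,
    weights = unlist(pool$weights %||% relatedPoolWeights()))
  net <- NetworkConfig(
    inChannels = y$network$in_channels %||% 4L,
    outChannels = y$network$out_channels %||% 3L,
    filters = unlist(y$network$filters %||% c(32L, 64L, 128L, 256L)),
    groups = y$network$groupnorm_groups %||% 8L,
    levels = y$network$levels %||% 3L,
    poolKind = pool$kind %||% "related", poolSpec = spec)
  cfg <- pipelineConfig(
    id = id, poolKind = net@poolKind, network = net, poolSpec = spec,
    epochs = y$training$epochs %||% 300L,
    batchSize = y$training$batch_size %||% 1L,
    learningRate = y$training$learning_rate %||% 1e-4,
    folds = y$training$folds %||% 5L,
    patchSize = unlist(y$training$patch_size %||% c(128L, 128L, 128L)),
    patchesPerCase = y$training$patches_per_case %||% 1L,
    seed = y$training$seed %||% 1L)
  aug <- y$augmentation
  if (!is.null(aug)) {
    pol <- cfg@augmentation
    if (!is.null(aug$p_rescale)) pol@pRescale <- aug$p_rescale
    if (!is.null(aug$rescale_range)) pol@rescaleRange <- unlist(aug$rescale_range)
    if (!is.null(aug$p_offset)) pol@pOffset <- aug$p_offset
    if (!is.null(aug$offset_range)) pol@offsetRange <- unlist(aug$offset_range)
    if (!is.null(aug$p_noise)) pol@pNoise <- aug$p_noise
    if (!is.null(aug$noise_sigma)) pol@noiseSigma <- aug$noise_sigma
    if (!is.null(aug$p_channel_drop)) pol@pChannelDrop <- aug$p_channel_drop
    if (!is.null(aug$p_flip_per_axis)) pol@pFlip <- aug$p_flip_per_axis
    validObject(pol)
    cfg@augmentation <- pol
  }
  if (!is.null(y$normalization$mode)) {
    cfg@normalization <- match.arg(y$normalization$mode, c("minmax", "zscore"))
  }
  validObject(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A down-scaled configuration for smoke training
#'
#' Tiny network (filters 4/8/16/32, groupnorm groups 4), 8^3 patches,
#' learning rate 1e-2, 4 patches per case per epoch, no augmentation.
#' Intended for fast correctness checks: a working implementation must
#' overfit the two noiseless 8^3 phantoms of [smokePhantomDataset()] with
#' it within ~30 epochs. The raised learning rate and multiple patches per
#' epoch compensate for the few optimization steps of such a short run;
#' the full-scale pipeline defaults (1e-4, one patch per case) are
#' unchanged.
#'
#' @param poolKind "related" or "max".
#' @param epochs training epochs (default 30).
#' @param seed integer RNG seed.
#' @return a [PipelineConfig].
#' @export
smokeConfig <- function(poolKind = "related", epochs = 30L, seed = 1L) {
  cfg <- pipelineConfig(
    id = "A", poolKind = poolKind,
    network = NetworkConfig(filters = c(4L, 8L, 16L, 32L), groups = 4L,
                            poolKind = poolKind),
    epochs = epochs, learningRate = 1e-2, patchSize = c(8L, 8L, 8L),
    patchesPerCase = 4L, seed = seed)
  cfg@augmentation <- AugmentationPolicy()   # all probabilities zero
  cfg
}
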