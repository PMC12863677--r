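## Training-time augmentations with the per-pipeline probabilities.
##
## All randomness is drawn from R's global RNG stream so that a caller who
## seeds the stream (set.seed or the training harness) gets bit-identical
## augmented samples. Intensity augmentations never touch the labels; axis
## flips are applied identically to image and labels.

#' Per-channel random intensity rescale
#'
#' With probability `p` independently per channel, multiplies that channel
#' by one factor sampled uniformly from `range`.
#'
#' @param image rank-4 numeric array.
#' @param p application probability per channel.
#' @param range uniform sampling interval of the factor.
#' @return augmented image.
#' @export
channelRescale <- function(image, p, range = c(0.9, 1.1)) {
  stopIfNotRank4(image)
  for (c in seq_len(dim(image)[1L])) {
    if (stats::runif(1) < p)
      image[c, , , ] <- image[c, , , ] * stats::runif(1, range[1L], range[2L])
  }
  image
}

#' Per-channel random intensity offset
#'
#' With probability `p` independently per channel, adds one constant
#' sampled uniformly from `range` to every voxel of that channel
#' (pipeline B only by default).
#'
#' @inheritParams channelRescale
#' @param range uniform sampling interval of the offset.
#' @return augmented image.
#' @export
channelOffset <- function(image, p, range = c(-0.1, 0.1)) {
  stopIfNotRank4(image)
  for (c in seq_len(dim(image)[1L])) {
    if (stats::runif(1) < p)
      image[c, , , ] <- image[c, , , ] + stats::runif(1, range[1L], range[2L])
  }
  image
}

#' Additive Gaussian noise
#'
#' With probability `p`, adds centered Gaussian noise with standard
#' deviation `sigma` to every voxel.
#'
#' @inheritParams channelRescale
#' @param sigma noise standard deviation (0.1 in both pipelines).
#' @return augmented image.
#' @export
addGaussianNoise <- function(image, p = 1, sigma = 0.1) {
  stopIfNotRank4(image)
  if (stats::runif(1) < p)
    image <- image + array(stats::rnorm(length(image), 0, sigma), dim(image))
  image
}

#' Input-channel dropping
#'
#' With probability `p`, zeroes all voxels of exactly one channel chosen
#' uniformly at random, simulating a missing MRI modality (pipeline A only
#' by default).
#'
#' @inheritParams channelRescale
#' @return augmented image.
#' @export
dropChannel <- function(image, p) {
  stopIfNotRank4(image)
  nc <- dim(image)[1L]
  if (nc < 2L) stop("channel dropping needs at least 2 channels")
  if (stats::runif(1) < p)
    image[sample.int(nc, 1L), , , ] <- 0
  image
}

#' Random per-axis mirroring
#'
#' Flips image and labels along each spatial axis independently with
#' probability `p` per axis, keeping them aligned.
#'
#' @inheritParams channelRescale
#' @param labels rank-3 array or `NULL`.
#' @return list with `image`, `labels` and the logical `flips` drawn.
#' @export
randomFlips <- function(image, labels = NULL, p) {
  stopIfNotRank4(image)
  flips <- stats::runif(3) < p
  if (any(flips)) {
    image <- flipAxes(image, flips)
    if (!is.null(labels)) labels <- flipAxes(labels, flips)
  }
  list(image = image, labels = labels, flips = flips)
}

#' Apply a full augmentation policy
#'
#' Applies, in fixed order: per-channel rescale, per-channel offset,
#' additive Gaussian noise, channel dropping, and per-axis flips. Only the
#' flips act on the labels.
#'
#' @param image rank-4 numeric array.
#' @param labels rank-3 integer array or `NULL`.
#' @param policy an [AugmentationPolicy].
#' @return list with augmented `image` and `labels`.
#' @seealso [pipelinePolicy()] for the shipped pipeline A/B presets.
#' @export
applyAugmentations <- function(image, labels, policy) {
  validObject(policy)
  image <- channelRescale(image, policy@pRescale, policy@rescaleRange)
  image <- channelOffset(image, policy@pOffset, policy@offsetRange)
  image <- addGaussianNoise(image, policy@pNoise, policy@noiseSigma)
  if (policy@pChannelDrop > 0) image <- dropChannel(image, policy@pChannelDrop)
  fl <- randomFlips(image, labels, policy@pFlip)
  list(image = fl$image, labels = fl$labels)
}

#' Shipped augmentation presets for pipelines A and B
#'
#' Pipeline A: rescale p = 0.7, no offset, noise sigma 0.1, channel drop
#' p = 0.16, per-axis flip p = 0.8. Pipeline B: rescale p = 0.2, offset
#' p = 1 over (-0.1, 0.1), noise sigma 0.1, no channel drop, per-axis flip
#' p = 0.5. Noise is applied with probability 1 in both (its application
#' probability is a package default, exposed here).
#'
#' @param id "A" or "B".
#' @return an [AugmentationPolicy].
#' @export
pipelinePolicy <- function(id = c("A", "B")) {
  switch(match.arg(id),
    A = AugmentationPolicy(pRescale = 0.7, pOffset = 0, pNoise = 1,
                           noiseSigma = 0.1, pChannelDrop = 0.16, pFlip = 0.8),
    B = AugmentationPolicy(pRescale = 0.2, pOffset = 1,
                           offsetRange = c(-0.1, 0.1), pNoise = 1,
                           noiseSigma = 0.1, pChannelDrop = 0, pFlip = 0.5))
}
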