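#' @import methods
NULL

## Channel order is fixed across the package: native T1, post-contrast T1,
## T2, and T2-FLAIR, matching the BraTS file suffixes.
BRATS_CHANNELS <- c("t1", "t1ce", "t2", "flair")

## Tumor sub-region labels: 0 background, 1 NCR/NET, 2 edema, 4 enhancing.
BRATS_LABELS <- c(0L, 1L, 2L, 4L)

#' MultiModalVolume: a 4-channel MRI volume
#'
#' Container for a rank-4 intensity array laid out as
#' (channel, depth, height, width) with voxel spacing metadata. The channel
#' order is fixed as T1, T1Gd (post-contrast), T2, T2-FLAIR.
#'
#' @slot data numeric 4D array, dim (channel, depth, height, width).
#' @slot spacing numeric voxel spacing in mm per spatial axis.
#' @slot channels character channel names.
#' @export
setClass("MultiModalVolume",
  representation(data = "array", spacing = "numeric", channels = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 4L)
      msg <- c(msg, "data must be a rank-4 array (channel, depth, height, width)")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(dim(object@data)) == 4L &&
        length(object@channels) != dim(object@data)[1L])
      msg <- c(msg, "channels must name each channel of data")
    if (is.null(msg)) TRUE else msg
  })

#' @param data numeric 4D array (channel, depth, height, width).
#' @param spacing numeric voxel spacing (mm) per spatial axis.
#' @param channels character channel names.
#' @rdname MultiModalVolume-class
#' @export
MultiModalVolume <- function(data, spacing = c(1, 1, 1),
                             channels = BRATS_CHANNELS[seq_len(dim(data)[1L])]) {
  new("MultiModalVolume", data = data, spacing = as.numeric(spacing),
      channels = channels)
}

#' LabelMap: an integer tumor sub-region volume
#'
#' Rank-3 integer volume over the BraTS label set \{0, 1, 2, 4\}
#' (background, NCR/NET, edema, enhancing tumor), aligned voxel-for-voxel
#' with a [MultiModalVolume].
#'
#' @slot data integer 3D array.
#' @slot spacing numeric voxel spacing in mm per spatial axis.
#' @export
setClass("LabelMap",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a rank-3 array")
    bad <- setdiff(unique(as.vector(object@data)), BRATS_LABELS)
    if (length(bad))
      msg <- c(msg, paste0("unknown label value(s): ",
                           paste(bad, collapse = ", ")))
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (is.null(msg)) TRUE else msg
  })

#' @param data integer 3D array with values in \{0, 1, 2, 4\}.
#' @param spacing numeric voxel spacing (mm).
#' @rdname LabelMap-class
#' @export
LabelMap <- function(data, spacing = c(1, 1, 1)) {
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, spacing = as.numeric(spacing))
}

#' PoolingSpec: window, stride and weights of the pooling operator
#'
#' Parameters of the Related 3D Pooling operator: the moving-window size,
#' its stride, and the weight vector applied position-wise to each window
#' before summation. The weights are non-negative and sum to 1, so constant
#' inputs are preserved; the default weights are the tuned coefficients
#' q = (0.03, 0.05, 0.07, 0.1, 0.13, 0.151, 0.214, 0.255) for a 2x2x2
#' window with stride 2.
#'
#' Weight-to-position mapping: the window is flattened in (depth, height,
#' width) raster order, i.e. `weights[1]` multiplies offset (0,0,0),
#' `weights[2]` offset (0,0,1), ..., `weights[8]` offset (1,1,1).
#'
#' @slot window integer window extent per spatial axis (voxels).
#' @slot stride integer stride between windows (voxels).
#' @slot weights numeric weight per window position, summing to 1.
#' @export
setClass("PoolingSpec",
  representation(window = "integer", stride = "integer", weights = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@window) != 3L || any(object@window < 1L))
      msg <- c(msg, "window must be 3 positive integers")
    if (length(object@stride) != 1L || object@stride < 1L)
      msg <- c(msg, "stride must be a single positive integer")
    if (length(object@weights) != prod(object@window))
      msg <- c(msg, sprintf(
        "weights has %d entries but the %s window needs %d",
        length(object@weights), paste(object@window, collapse = "x"),
        prod(object@window)))
    if (any(object@weights < 0))
      msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, sprintf("weights must sum to 1 (got %.12f)",
                            sum(object@weights)))
    if (length(object@window) == 3L && any(object@window > object@stride))
      msg <- c(msg, "overlapping windows (window > stride) are not supported")
    if (is.null(msg)) TRUE else msg
  })

#' Default Related 3D Pooling weights
#'
#' The eight tuned window coefficients, in (depth, height, width) raster
#' order; they sum to exactly 1.
#'
#' @return numeric vector of length 8.
#' @export
relatedPoolWeights <- function() {
  c(0.03, 0.05, 0.07, 0.1, 0.13, 0.151, 0.214, 0.255)
}

#' @param window integer triple, window extent per axis.
#' @param stride integer stride.
#' @param weights numeric weights, one per window position.
#' @rdname PoolingSpec-class
#' @export
PoolingSpec <- function(window = c(2L, 2L, 2L), stride = 2L,
                        weights = relatedPoolWeights()) {
  new("PoolingSpec", window = as.integer(window), stride = as.integer(stride),
      weights = as.numeric(weights))
}

#' AugmentationPolicy: stochastic training-time augmentation settings
#'
#' Per-sample augmentation probabilities and ranges. Intensity augmentations
#' (rescale, offset, noise, channel drop) touch only the image; axis flips
#' are applied identically to image and labels.
#'
#' @slot pRescale probability of multiplying each channel by a random factor.
#' @slot rescaleRange uniform sampling range of the rescale factor.
#' @slot pOffset probability of adding a random constant to each channel.
#' @slot offsetRange uniform sampling range of the offset.
#' @slot pNoise probability of adding voxelwise Gaussian noise.
#' @slot noiseSigma standard deviation of the additive noise.
#' @slot pChannelDrop probability of zeroing one randomly chosen channel.
#' @slot pFlip probability of mirroring, applied independently per spatial axis.
#' @export
setClass("AugmentationPolicy",
  representation(pRescale = "numeric", rescaleRange = "numeric",
                 pOffset = "numeric", offsetRange = "numeric",
                 pNoise = "numeric", noiseSigma = "numeric",
                 pChannelDrop = "numeric", pFlip = "numeric"),
  validity = function(object) {
    msg <- NULL
    ps <- c(object@pRescale, object@pOffset, object@pNoise,
            object@pChannelDrop, object@pFlip)
    if (any(ps < 0 | ps > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
    if (length(object@rescaleRange) != 2L || diff(object@rescaleRange) < 0)
      msg <- c(msg, "rescaleRange must be an ordered pair")
    if (length(object@offsetRange) != 2L || diff(object@offsetRange) < 0)
      msg <- c(msg, "offsetRange must be an ordered pair")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param pRescale,rescaleRange,pOffset,offsetRange,pNoise,noiseSigma,pChannelDrop,pFlip
#'   see the class slots.
#' @rdname AugmentationPolicy-class
#' @export
AugmentationPolicy <- function(pRescale = 0, rescaleRange = c(0.9, 1.1),
                               pOffset = 0, offsetRange = c(-0.1, 0.1),
                               pNoise = 0, noiseSigma = 0.1,
                               pChannelDrop = 0, pFlip = 0) {
  new("AugmentationPolicy", pRescale = pRescale, rescaleRange = rescaleRange,
      pOffset = pOffset, offsetRange = offsetRange, pNoise = pNoise,
      noiseSigma = noiseSigma, pChannelDrop = pChannelDrop, pFlip = pFlip)
}

#' NetworkConfig: architecture of the 3D U-Net
#'
#' The encoder-decoder has `levels` down-sampling stages (default 3, which
#' pairs with the divisible-by-8 padding contract), each encoder stage being
#' two 3x3x3 convolutions with group normalization and ReLU followed by the
#' configured pooling; two further convolutional blocks form the bottleneck;
#' the decoder mirrors the encoder with transposed-convolution up-sampling
#' and concatenation skips, and a 1x1x1 convolution with sigmoid produces
#' the 3 region probability channels (ET, TC, WT).
#'
#' @slot inChannels integer, input channels (4 MRI modalities).
#' @slot outChannels integer, output channels (3 nested tumor regions).
#' @slot filters integer vector of encoder widths, length `levels + 1`
#'   (the last entry is the bottleneck width).
#' @slot groups integer, group count of group normalization; must divide
#'   every filter width.
#' @slot levels integer, number of down-sampling stages.
#' @slot poolKind "related" or "max".
#' @slot poolSpec a [PoolingSpec].
#' @export
setClass("NetworkConfig",
  representation(inChannels = "integer", outChannels = "integer",
                 filters = "integer", groups = "integer", levels = "integer",
                 poolKind = "character", poolSpec = "PoolingSpec"),
  validity = function(object) {
    msg <- NULL
    if (length(object@filters) != object@levels + 1L)
      msg <- c(msg, "filters must have levels + 1 entries")
    if (any(object@filters %% object@groups != 0L))
      msg <- c(msg, "groups must divide every filter width")
    if (object@outChannels != 3L)
      msg <- c(msg, "outChannels must be 3 (ET, TC, WT probability maps)")
    if (!object@poolKind %in% c("related", "max"))
      msg <- c(msg, "poolKind must be 'related' or 'max'")
    if (is.null(msg)) TRUE else msg
  })

#' @param inChannels,outChannels,filters,groups,levels,poolKind,poolSpec
#'   see the class slots.
#' @rdname NetworkConfig-class
#' @export
NetworkConfig <- function(inChannels = 4L, outChannels = 3L,
                          filters = c(32L, 64L, 128L, 256L), groups = 8L,
                          levels = 3L, poolKind = "related",
                          poolSpec = PoolingSpec()) {
  new("NetworkConfig", inChannels = as.integer(inChannels),
      outChannels = as.integer(outChannels), filters = as.integer(filters),
      groups = as.integer(groups), levels = as.integer(levels),
      poolKind = poolKind, poolSpec = poolSpec)
}

#' UNet3D: a built network (configuration + parameters)
#'
#' @slot config the [NetworkConfig] the network was built from.
#' @slot params nested list of parameter arrays.
#' @export
setClass("UNet3D", representation(config = "NetworkConfig", params = "list"))

#' PipelineConfig: everything distinguishing training pipeline A from B
#'
#' Pipeline A uses min-max percentile normalization with channel dropping
#' and frequent flips; pipeline B uses z-score normalization with intensity
#' offsets and rarer flips. Both share the network architecture and the
#' optimization recipe (Adam, constant learning rate 1e-4, batch size 1,
#' 300 epochs, five-fold cross-validation).
#'
#' @slot id "A" or "B".
#' @slot normalization "minmax" or "zscore".
#' @slot augmentation an [AugmentationPolicy].
#' @slot network a [NetworkConfig].
#' @slot epochs integer training epochs.
#' @slot batchSize integer (1: update after every sample).
#' @slot learningRate numeric constant Adam step size.
#' @slot optimizer character, currently "adam".
#' @slot folds integer cross-validation folds.
#' @slot patchSize integer training patch extent per axis.
#' @slot patchesPerCase integer random patches drawn per case per epoch.
#' @slot seed integer RNG seed.
#' @export
setClass("PipelineConfig",
  representation(id = "character", normalization = "character",
                 augmentation = "AugmentationPolicy", network = "NetworkConfig",
                 epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", optimizer = "character",
                 folds = "integer", patchSize = "integer",
                 patchesPerCase = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@id %in% c("A", "B")) msg <- c(msg, "id must be 'A' or 'B'")
    if (!object@normalization %in% c("minmax", "zscore"))
      msg <- c(msg, "normalization must be 'minmax' or 'zscore'")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (object@folds < 2L) msg <- c(msg, "folds must be >= 2")
    if (length(object@patchSize) != 3L || any(object@patchSize < 1L))
      msg <- c(msg, "patchSize must be 3 positive integers")
    if (object@patchesPerCase < 1L) msg <- c(msg, "patchesPerCase must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' RegionMasks: binary masks of the three nested tumor regions
#'
#' Holds binary (logical) rank-3 masks for enhancing tumor (ET), tumor core
#' (TC) and whole tumor (WT). After nesting enforcement (see [binarize])
#' they satisfy ET \eqn{\subseteq} TC \eqn{\subseteq} WT.
#'
#' @slot et,tc,wt logical 3D arrays of identical shape.
#' @export
setClass("RegionMasks",
  representation(et = "array", tc = "array", wt = "array"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@et)
    if (length(d) != 3L) msg <- c(msg, "masks must be rank-3 arrays")
    if (!identical(d, dim(object@tc)) || !identical(d, dim(object@wt)))
      msg <- c(msg, "ET, TC and WT masks must share one shape")
    if (!is.logical(object@et) || !is.logical(object@tc) ||
        !is.logical(object@wt))
      msg <- c(msg, "masks must be logical arrays")
    if (is.null(msg)) TRUE else msg
  })

#' @param et,tc,wt logical 3D arrays.
#' @rdname RegionMasks-class
#' @export
RegionMasks <- function(et, tc, wt) {
  new("RegionMasks", et = et, tc = tc, wt = wt)
}

#' PhantomSpec: parameters of a synthetic BraTS-like case
#'
#' Describes a brain-shaped ellipsoid of non-zero intensity on a zero
#' background containing nested tumor ellipsoids (WT shell = edema, TC
#' shell = NCR/NET, core = ET) with modality-dependent mean contrast and
#' additive Gaussian noise, clipped at zero.
#'
#' @slot shape integer spatial extent (depth, height, width).
#' @slot brainRadii numeric semi-axes of the brain ellipsoid (voxels).
#' @slot tumorCenter numeric tumor center (voxel coordinates).
#' @slot regionRadii 3x3 numeric matrix of semi-axes, rows WT, TC, ET
#'   (strictly nested).
#' @slot contrast 4x4 numeric matrix of mean intensities, rows are the
#'   modalities (t1, t1ce, t2, flair), columns the tissues
#'   (brain, edema, ncr, et).
#' @slot noiseSigma numeric additive Gaussian noise level.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", brainRadii = "numeric",
                 tumorCenter = "numeric", regionRadii = "matrix",
                 contrast = "matrix", noiseSigma = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@shape) != 3L || any(object@shape < 4L))
      msg <- c(msg, "shape must be 3 integers >= 4")
    if (!identical(dim(object@regionRadii), c(3L, 3L)))
      msg <- c(msg, "regionRadii must be a 3x3 matrix (rows WT, TC, ET)")
    else {
      if (!all(object@regionRadii[1, ] > object@regionRadii[2, ]) ||
          !all(object@regionRadii[2, ] > object@regionRadii[3, ]))
        msg <- c(msg, "region radii must be strictly nested: WT > TC > ET")
      if (any(object@regionRadii <= 0))
        msg <- c(msg, "region radii must be positive")
    }
    if (!identical(dim(object@contrast), c(4L, 4L)))
      msg <- c(msg, "contrast must be a 4x4 matrix (modality x tissue)")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

## ---- show methods ----------------------------------------------------------

setMethod("show", "MultiModalVolume", function(object) {
  d <- dim(object@data)
  cat("MultiModalVolume:", d[1L], "channel(s) [",
      paste(object@channels, collapse = ", "), "],",
      paste(d[-1L], collapse = " x "), "voxels,",
      paste(object@spacing, collapse = " x "), "mm\n")
})

setMethod("show", "LabelMap", function(object) {
  tab <- table(factor(as.vector(object@data), levels = BRATS_LABELS))
  cat("LabelMap:", paste(dim(object@data), collapse = " x "), "voxels;",
      paste(sprintf("label %s: %d", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
})

setMethod("show", "PoolingSpec", function(object) {
  cat("PoolingSpec: window", paste(object@window, collapse = "x"),
      "stride", object@stride, "\n  weights:",
      paste(format(object@weights), collapse = ", "), "\n")
})

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig: 3D U-Net,", object@inChannels, "->",
      object@outChannels, "channels;", object@levels, "levels; filters",
      paste(object@filters, collapse = "/"), ";", object@poolKind,
      "pooling; groupnorm groups", object@groups, "\n")
})

setMethod("show", "UNet3D", function(object) {
  cat("UNet3D with", parameterCount(object), "parameters\n")
  show(object@config)
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig", object@id, ":", object@normalization,
      "normalization,", object@network@poolKind, "pooling,",
      object@epochs, "epochs, lr", object@learningRate, "\n")
})

setMethod("show", "RegionMasks", function(object) {
  cat("RegionMasks:", paste(dim(object@et), collapse = " x "),
      sprintf("voxels; |ET|=%d |TC|=%d |WT|=%d; nested: %s\n",
              sum(object@et), sum(object@tc), sum(object@wt),
              isNested(object)))
})

## ---- accessors -------------------------------------------------------------

#' Accessors for the container classes
#'
#' `volArray` and `labelArray` return the underlying arrays, `spacing` the
#' voxel spacing in mm, `channelNames` the modality names, and `regionMask`
#' one of the ET/TC/WT masks. `isNested` reports whether the region masks
#' satisfy ET \eqn{\subseteq} TC \eqn{\subseteq} WT.
#'
#' @param x a container object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volArray", function(x) standardGeneric("volArray"))
#' @rdname accessors
setMethod("volArray", "MultiModalVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
setMethod("labelArray", "LabelMap", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
setMethod("spacing", "MultiModalVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "LabelMap", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
setMethod("channelNames", "MultiModalVolume", function(x) x@channels)

#' @rdname accessors
#' @param region one of "ET", "TC", "WT".
#' @export
setGeneric("regionMask", function(x, region) standardGeneric("regionMask"))
#' @rdname accessors
setMethod("regionMask", "RegionMasks", function(x, region) {
  switch(match.arg(region, c("ET", "TC", "WT")),
         ET = x@et, TC = x@tc, WT = x@wt)
})

#' @rdname accessors
#' @export
setGeneric("isNested", function(x) standardGeneric("isNested"))
#' @rdname accessors
setMethod("isNested", "RegionMasks", function(x) {
  !any(x@et & !x@tc) && !any(x@tc & !x@wt)
})

#' @rdname accessors
#' @export
setGeneric("networkConfig", function(x) standardGeneric("networkConfig"))
#' @rdname accessors
setMethod("networkConfig", "UNet3D", function(x) x@config)
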