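## Full-volume inference, snapshot-ensemble probability averaging,
## thresholding with nesting enforcement, and the BraTS label algebra in
## both directions (label 4 = ET, labels {1,4} = TC, labels {1,2,4} = WT;
## NCR/NET = TC - ET, edema = WT - TC).

#' Full-volume inference for one case
#'
#' Applies the pipeline's normalization, crops to the brain bounding box,
#' zero-pads each spatial dimension to a multiple of `2^levels` (8 for the
#' default architecture), runs one forward pass, removes the padding, and
#' restores the probabilities onto the original voxel grid (zero outside
#' the brain crop).
#'
#' @param network a trained [UNet3D].
#' @param image a [MultiModalVolume] or rank-4 array (raw intensities).
#' @param pipeline a [PipelineConfig]; its normalization mode is used.
#' @return rank-4 array (3, depth, height, width) of probabilities aligned
#'   with the input grid.
#' @export
predictCase <- function(network, image, pipeline = pipelineConfig("A")) {
  x <- asVolumeArray(image)
  norm <- normalizeVolume(x, pipeline@normalization)
  cr <- cropToBrain(norm)
  mult <- as.integer(2^network@config@levels)
  pd <- padToMultiple(cr$image, mult)
  fw <- netForward(network, pd$image, train = FALSE)
  probs <- unpad(fw$y, pd$pad)
  uncrop(probs, cr$crop)
}

#' Average a snapshot ensemble of probability maps
#'
#' Voxelwise arithmetic mean of per-region probability maps, the fusion
#' rule of the snapshot ensemble. Averaging is order-invariant and
#' idempotent on identical maps.
#'
#' @param maps list of rank-4 probability arrays of identical shape.
#' @return rank-4 array, the mean map.
#' @export
ensembleAverage <- function(maps) {
  if (!is.list(maps) || length(maps) == 0L)
    stop("maps must be a non-empty list of probability arrays")
  d <- dim(maps[[1L]])
  for (m in maps)
    if (!identical(dim(m), d)) stop("all probability maps must share one shape")
  Reduce(`+`, maps) / length(maps)
}

#' Threshold probabilities into nested region masks
#'
#' Binarizes each region channel at `tau` (voxels with probability exactly
#' `tau` are positive) and then enforces the anatomical nesting
#' ET \eqn{\subseteq} TC \eqn{\subseteq} WT by union toward the larger
#' regions: TC := TC | ET, WT := WT | TC.
#'
#' @param map rank-4 probability array (channels ET, TC, WT).
#' @param tau threshold (default 0.5).
#' @return a nested [RegionMasks].
#' @export
binarize <- function(map, tau = 0.5) {
  stopIfNotRank4(map, "probability map")
  if (dim(map)[1L] != 3L) stop("probability map must have 3 channels")
  et <- map[1L, , , ] >= tau
  tc <- (map[2L, , , ] >= tau) | et
  wt <- (map[3L, , , ] >= tau) | tc
  RegionMasks(et = et, tc = tc, wt = wt)
}

#' Reconstruct a BraTS label map from nested region masks
#'
#' Label 4 where ET, label 1 where TC and not ET (NCR/NET = TC - ET),
#' label 2 where WT and not TC (edema = WT - TC), 0 elsewhere.
#'
#' @param masks a nested [RegionMasks] (from [binarize()]).
#' @param spacing voxel spacing for the returned [LabelMap].
#' @return a [LabelMap].
#' @export
reconstructLabels <- function(masks, spacing = c(1, 1, 1)) {
  validObject(masks)
  if (!isNested(masks))
    stop("masks are not nested (ET within TC within WT); binarize() first")
  lab <- array(0L, dim(masks@et))
  lab[masks@wt] <- 2L
  lab[masks@tc] <- 1L
  lab[masks@et] <- 4L
  LabelMap(lab, spacing)
}

#' Region masks from a BraTS label map
#'
#' ET = (label 4); TC = (label 1 or 4); WT = (label 1, 2 or 4). The inverse
#' of [reconstructLabels()].
#'
#' @param labels a [LabelMap] or rank-3 integer array over \{0, 1, 2, 4\}.
#' @return a nested [RegionMasks].
#' @export
regionsFromLabels <- function(labels) {
  la <- if (is(labels, "LabelMap")) labelArray(labels) else labels
  bad <- setdiff(unique(as.vector(la)), BRATS_LABELS)
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  RegionMasks(et = array(la == 4L, dim(la)),
              tc = array(la == 1L | la == 4L, dim(la)),
              wt = array(la == 1L | la == 2L | la == 4L, dim(la)))
}
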