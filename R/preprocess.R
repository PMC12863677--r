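## Intensity normalization, brain cropping, padding and patch extraction.
##
## Both normalization modes operate per channel on the *non-zero* voxels
## only: in skull-stripped BraTS volumes the exact-zero background carries
## no signal and must remain exactly zero afterwards.

#' Min-max percentile normalization (pipeline A)
#'
#' Per channel, computes the 1st and 99th percentiles (linear-interpolation
#' convention) of the non-zero voxels, clips non-zero voxels into that
#' range, and maps it affinely onto \[0, 1\]. Exact-zero voxels are left at
#' zero.
#'
#' @param volume numeric rank-4 array or [MultiModalVolume].
#' @param pLow,pHigh percentiles in \[0, 100\] (defaults 1 and 99).
#' @return object of the same kind as `volume`, normalized.
#' @export
minmaxNormalize <- function(volume, pLow = 1, pHigh = 99) {
  x <- asVolumeArray(volume)
  for (c in seq_len(dim(x)[1L])) {
    ch <- x[c, , , ]
    nz <- ch != 0
    if (!any(nz)) {
      warning(sprintf("channel %d is entirely zero; left unchanged", c))
      next
    }
    v <- ch[nz]
    lo <- linQuantile(v, pLow / 100)
    hi <- linQuantile(v, pHigh / 100)
    if (hi == lo) {
      warning(sprintf(
        "channel %d has a degenerate percentile range; non-zero voxels set to 0",
        c))
      ch[nz] <- 0
    } else {
      ch[nz] <- (pmin(pmax(v, lo), hi) - lo) / (hi - lo)
    }
    x[c, , , ] <- ch
  }
  if (is(volume, "MultiModalVolume"))
    MultiModalVolume(x, spacing(volume), channelNames(volume))
  else x
}

#' Z-score normalization (pipeline B)
#'
#' Per channel, maps non-zero voxels to zero mean and unit standard
#' deviation using the population (divide-by-n) standard deviation over the
#' non-zero voxels. Exact-zero voxels are left at zero.
#'
#' @param volume numeric rank-4 array or [MultiModalVolume].
#' @return object of the same kind as `volume`, normalized.
#' @export
zscoreNormalize <- function(volume) {
  x <- asVolumeArray(volume)
  for (c in seq_len(dim(x)[1L])) {
    ch <- x[c, , , ]
    nz <- ch != 0
    if (!any(nz)) {
      warning(sprintf("channel %d is entirely zero; left unchanged", c))
      next
    }
    v <- ch[nz]
    mu <- mean(v)
    sd0 <- sqrt(mean((v - mu)^2))
    if (sd0 == 0) {
      warning(sprintf(
        "channel %d has zero spread; non-zero voxels set to 0", c))
      ch[nz] <- 0
    } else {
      ch[nz] <- (v - mu) / sd0
    }
    x[c, , , ] <- ch
  }
  if (is(volume, "MultiModalVolume"))
    MultiModalVolume(x, spacing(volume), channelNames(volume))
  else x
}

#' Apply the normalization mode of a pipeline
#'
#' @param volume numeric rank-4 array or [MultiModalVolume].
#' @param mode "minmax" (pipeline A) or "zscore" (pipeline B).
#' @return normalized volume.
#' @export
normalizeVolume <- function(volume, mode = c("minmax", "zscore")) {
  switch(match.arg(mode), minmax = minmaxNormalize(volume),
         zscore = zscoreNormalize(volume))
}

#' Crop to the brain bounding box
#'
#' Finds the smallest axis-aligned box containing every voxel that is
#' non-zero in *any* channel, and crops image (and labels, when given)
#' to it. The returned crop record allows exact restoration into the
#' original grid via [uncrop()].
#'
#' @param image a [MultiModalVolume] or rank-4 array.
#' @param labels an aligned [LabelMap] or rank-3 array, or `NULL`.
#' @return list with `image`, `labels` (or `NULL`) and `crop`, where `crop`
#'   is a list with per-axis 1-based inclusive `start`/`stop` indices and
#'   the original spatial `shape`.
#' @export
cropToBrain <- function(image, labels = NULL) {
  x <- asVolumeArray(image)
  support <- apply(x != 0, c(2, 3, 4), any)
  if (!any(support)) stop("image is entirely zero: no brain support")
  idx <- which(support, arr.ind = TRUE)
  start <- apply(idx, 2, min)
  stop_ <- apply(idx, 2, max)
  crop <- list(start = as.integer(start), stop = as.integer(stop_),
               shape = spatialDim(x))
  ci <- x[, start[1]:stop_[1], start[2]:stop_[2], start[3]:stop_[3],
          drop = FALSE]
  cl <- NULL
  if (!is.null(labels)) {
    la <- if (is(labels, "LabelMap")) labelArray(labels) else labels
    cl <- la[start[1]:stop_[1], start[2]:stop_[2], start[3]:stop_[3],
             drop = FALSE]
    if (is(labels, "LabelMap")) cl <- LabelMap(cl, spacing(labels))
  }
  if (is(image, "MultiModalVolume"))
    ci <- MultiModalVolume(ci, spacing(image), channelNames(image))
  list(image = ci, labels = cl, crop = crop)
}

#' Restore a cropped array into its original grid
#'
#' Inverse of [cropToBrain()]: embeds a cropped rank-3 or rank-4 array back
#' into a zero array of the original spatial shape.
#'
#' @param x cropped rank-3 or rank-4 array.
#' @param crop crop record from [cropToBrain()].
#' @return array of the original spatial shape.
#' @export
uncrop <- function(x, crop) {
  nd <- length(dim(x))
  rng <- lapply(1:3, function(a) crop$start[a]:crop$stop[a])
  if (nd == 4L) {
    out <- array(0, c(dim(x)[1L], crop$shape))
    out[, rng[[1L]], rng[[2L]], rng[[3L]]] <- x
  } else {
    out <- array(if (is.integer(x)) 0L else 0, crop$shape)
    out[rng[[1L]], rng[[2L]], rng[[3L]]] <- x
  }
  out
}

#' Zero-pad spatial dims to a multiple
#'
#' Pads each spatial axis with zeros to the next multiple of `multiple`
#' (8 by default, matching the three down-sampling stages of the network),
#' splitting the padding as symmetrically as possible with the extra voxel
#' on the trailing side when odd.
#'
#' @param image rank-4 (or rank-3) numeric array.
#' @param multiple integer >= 1.
#' @return list with `image` (padded) and `pad`, a list of per-axis
#'   `c(before, after)` widths usable with [unpad()].
#' @export
padToMultiple <- function(image, multiple = 8L) {
  stopifnot(multiple >= 1L)
  nd <- length(dim(image))
  sp <- if (nd == 4L) spatialDim(image) else dim(image)
  target <- ceiling(sp / multiple) * multiple
  extra <- target - sp
  before <- extra %/% 2L
  after <- extra - before
  pad <- list(before = as.integer(before), after = as.integer(after))
  if (all(extra == 0L)) return(list(image = image, pad = pad))
  if (nd == 4L) {
    out <- array(0, c(dim(image)[1L], target))
    out[, before[1] + seq_len(sp[1]), before[2] + seq_len(sp[2]),
        before[3] + seq_len(sp[3])] <- image
  } else {
    out <- array(if (is.integer(image)) 0L else 0, target)
    out[before[1] + seq_len(sp[1]), before[2] + seq_len(sp[2]),
        before[3] + seq_len(sp[3])] <- image
  }
  list(image = out, pad = pad)
}

#' Remove padding added by [padToMultiple()]
#'
#' @param x padded rank-3 or rank-4 array.
#' @param pad pad record from [padToMultiple()].
#' @return the unpadded array.
#' @export
unpad <- function(x, pad) {
  nd <- length(dim(x))
  sp <- if (nd == 4L) spatialDim(x) else dim(x)
  rng <- lapply(1:3, function(a)
    (pad$before[a] + 1L):(sp[a] - pad$after[a]))
  if (nd == 4L) x[, rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
  else x[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
}

#' Random fixed-size patch extraction
#'
#' Draws a spatially aligned random patch from image and labels, with
#' offsets sampled uniformly over the valid range from the current RNG
#' stream. Inputs smaller than the patch along an axis are zero-padded up
#' to the patch size first, split as symmetrically as possible (the same
#' convention as [padToMultiple()], so that training patches and padded
#' full-volume inference agree on the voxel grid).
#'
#' @param image rank-4 numeric array.
#' @param labels rank-3 integer array aligned with `image`, or `NULL`.
#' @param size integer patch extent per axis (default 128^3, the training
#'   patch of both pipelines).
#' @return list with `image` and `labels` patches and the 0-based `offset`
#'   used.
#' @export
randomCrop <- function(image, labels = NULL, size = c(128L, 128L, 128L)) {
  size <- as.integer(size)
  sp <- spatialDim(image)
  if (any(sp < size)) {
    before <- pmax(size - sp, 0L) %/% 2L
    target <- pmax(sp, size)
    padded <- array(0, c(dim(image)[1L], target))
    padded[, before[1] + seq_len(sp[1]), before[2] + seq_len(sp[2]),
           before[3] + seq_len(sp[3])] <- image
    image <- padded
    if (!is.null(labels)) {
      lp <- array(0L, target)
      lp[before[1] + seq_len(sp[1]), before[2] + seq_len(sp[2]),
         before[3] + seq_len(sp[3])] <- labels
      labels <- lp
    }
    sp <- target
  }
  maxOff <- sp - size
  off <- vapply(maxOff, function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
  rng <- lapply(1:3, function(a) off[a] + seq_len(size[a]))
  list(image = image[, rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE],
       labels = if (is.null(labels)) NULL
                else labels[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE],
       offset = off)
}
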