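## Related 3D Pooling: the down-sampling operator at the core of the package.
##
## Each non-overlapping window of the input is flattened in (depth, height,
## width) raster order, multiplied position-wise by a fixed non-negative
## weight vector q with sum(q) = 1 ("fuzzy measure coefficients"), and the
## products are summed to a single output voxel. Unlike max pooling this
## keeps a contribution from every voxel of the window, preserving local
## relationships; because sum(q) = 1 the operator preserves constants and is
## affine-equivariant.

## Window offsets in (depth, height, width) raster order: depth slowest,
## width fastest, matching the weight layout q[1] <-> (0,0,0) ...
## q[n] <-> (wd-1, wh-1, ww-1).
windowOffsets <- function(window) {
  off <- expand.grid(w = seq_len(window[3L]) - 1L,
                     h = seq_len(window[2L]) - 1L,
                     d = seq_len(window[1L]) - 1L)
  cbind(d = off$d, h = off$h, w = off$w)
}

checkPoolInput <- function(x, stride) {
  stopIfNotRank4(x)
  sp <- spatialDim(x)
  bad <- which(sp %% stride != 0L)
  if (length(bad))
    stop(sprintf(
      "spatial axis %d (extent %d) is not divisible by the stride %d",
      bad[1L], sp[bad[1L]], stride), call. = FALSE)
  invisible(sp)
}

## Extract the stack of window-position slices of x as a list of
## (C x nOut) matrices, one per window offset (raster order).
poolSlices <- function(x, window, stride) {
  sp <- spatialDim(x)
  out <- sp %/% stride
  starts <- lapply(1:3, function(a) (seq_len(out[a]) - 1L) * stride + 1L)
  off <- windowOffsets(window)
  n <- prod(out)
  C <- dim(x)[1L]
  lapply(seq_len(nrow(off)), function(k) {
    m <- x[, starts[[1L]] + off[k, 1L],
             starts[[2L]] + off[k, 2L],
             starts[[3L]] + off[k, 3L], drop = FALSE]
    dim(m) <- c(C, n)
    m
  })
}

#' Related 3D Pooling
#'
#' Down-samples a (channel, depth, height, width) volume by replacing each
#' non-overlapping window with the weighted sum of its voxels, using the
#' position-wise weights of `spec` (see [PoolingSpec] for the raster-order
#' weight mapping). Channels are processed independently; each spatial
#' extent shrinks by the stride factor (2 by default).
#'
#' @param volume numeric rank-4 array or [MultiModalVolume].
#' @param spec a [PoolingSpec]; defaults to the tuned 2x2x2 operator.
#' @return numeric rank-4 array with spatial dims divided by `spec@stride`.
#' @seealso [maxPool3d()], [poolOracle()]
#' @examples
#' x <- array(seq_len(2 * 4 * 4 * 4), c(2, 4, 4, 4))
#' dim(relatedPool3d(x))  # 2 2 2 2
#' @export
relatedPool3d <- function(volume, spec = PoolingSpec()) {
  x <- asVolumeArray(volume)
  validObject(spec)
  checkPoolInput(x, spec@stride)
  sl <- poolSlices(x, spec@window, spec@stride)
  acc <- spec@weights[1L] * sl[[1L]]
  for (k in seq_along(sl)[-1L]) acc <- acc + spec@weights[k] * sl[[k]]
  out <- spatialDim(x) %/% spec@stride
  array(acc, c(dim(x)[1L], out))
}

#' 3D max pooling
#'
#' The conventional baseline: each output voxel is the maximum over its
#' window.
#'
#' @param volume numeric rank-4 array or [MultiModalVolume].
#' @param window integer triple window extent.
#' @param stride integer stride.
#' @return numeric rank-4 array with spatial dims divided by `stride`.
#' @export
maxPool3d <- function(volume, window = c(2L, 2L, 2L), stride = 2L) {
  x <- asVolumeArray(volume)
  window <- as.integer(window)
  stride <- as.integer(stride)
  if (any(window > stride))
    stop("overlapping windows (window > stride) are not supported",
         call. = FALSE)
  checkPoolInput(x, stride)
  sl <- poolSlices(x, window, stride)
  acc <- sl[[1L]]
  for (k in seq_along(sl)[-1L]) acc <- pmax(acc, sl[[k]])
  out <- spatialDim(x) %/% stride
  array(acc, c(dim(x)[1L], out))
}

## Max pooling that also returns the raster-order window position of each
## maximum (first occurrence on ties); used by the network backward pass.
maxPool3dWithArg <- function(x, window = c(2L, 2L, 2L), stride = 2L) {
  checkPoolInput(x, stride)
  sl <- poolSlices(x, window, stride)
  acc <- sl[[1L]]
  arg <- array(1L, dim(acc))
  for (k in seq_along(sl)[-1L]) {
    better <- sl[[k]] > acc
    acc[better] <- sl[[k]][better]
    arg[better] <- k
  }
  out <- spatialDim(x) %/% stride
  list(y = array(acc, c(dim(x)[1L], out)), arg = arg)
}

## Scatter an upstream gradient dy through a pooling layer back to the
## input grid. For related pooling d y / d x_i = q_i; for max pooling the
## gradient routes to the argmax voxel of each window.
poolBackward <- function(dy, inDim, spec, kind, arg = NULL) {
  stride <- spec@stride
  out <- inDim[-1L] %/% stride
  starts <- lapply(1:3, function(a) (seq_len(out[a]) - 1L) * stride + 1L)
  off <- windowOffsets(spec@window)
  dx <- array(0, inDim)
  dyM <- dy
  dim(dyM) <- c(inDim[1L], prod(out))
  for (k in seq_len(nrow(off))) {
    id <- starts[[1L]] + off[k, 1L]
    ih <- starts[[2L]] + off[k, 2L]
    iw <- starts[[3L]] + off[k, 3L]
    cur <- dx[, id, ih, iw, drop = FALSE]
    if (kind == "related") {
      dx[, id, ih, iw] <- cur + array(spec@weights[k] * dyM, c(inDim[1L], out))
    } else {
      sel <- arg == k
      contrib <- array(0, dim(dyM))
      contrib[sel] <- dyM[sel]
      dx[, id, ih, iw] <- cur + array(contrib, c(inDim[1L], out))
    }
  }
  dx
}

#' Brute-force pooling oracle
#'
#' Reference implementation of related, max and average pooling computed by
#' explicit nested loops over output voxels and window positions, with no
#' vectorized shortcuts. Intended for tests only; it is deliberately slow.
#'
#' @param volume numeric rank-4 array.
#' @param spec a [PoolingSpec] (weights are ignored for max/average).
#' @param mode one of "related", "max", "average".
#' @return numeric rank-4 array.
#' @export
poolOracle <- function(volume, spec = PoolingSpec(),
                       mode = c("related", "max", "average")) {
  mode <- match.arg(mode)
  x <- asVolumeArray(volume)
  validObject(spec)
  checkPoolInput(x, spec@stride)
  sp <- spatialDim(x)
  out <- sp %/% spec@stride
  C <- dim(x)[1L]
  y <- array(NA_real_, c(C, out))
  off <- windowOffsets(spec@window)
  for (c in seq_len(C))
    for (od in seq_len(out[1L]))
      for (oh in seq_len(out[2L]))
        for (ow in seq_len(out[3L])) {
          base <- (c(od, oh, ow) - 1L) * spec@stride + 1L
          vals <- numeric(nrow(off))
          for (k in seq_len(nrow(off)))
            vals[k] <- x[c, base[1L] + off[k, 1L], base[2L] + off[k, 2L],
                         base[3L] + off[k, 3L]]
          y[c, od, oh, ow] <- switch(mode,
            related = sum(spec@weights * vals),
            max = max(vals),
            average = mean(vals))
        }
  y
}
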