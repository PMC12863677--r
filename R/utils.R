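## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## seed = NULL leaves the global RNG stream untouched (and consumed).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a reproducible child seed from a base seed, staying inside the
## 32-bit signed integer range.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483587)
}

## dim() of the spatial axes of a (channel, depth, height, width) array.
spatialDim <- function(x) dim(x)[-1L]

stopIfNotRank4 <- function(x, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop(what, " must be a rank-4 array (channel, depth, height, width)",
         call. = FALSE)
}

## Coerce MultiModalVolume or raw array to the raw (C, D, H, W) array.
asVolumeArray <- function(x) {
  if (is(x, "MultiModalVolume")) return(x@data)
  stopIfNotRank4(x)
  x
}

## Reverse index vector for mirroring one axis.
flipIndex <- function(n) seq.int(n, 1L)

## Apply per-axis mirroring to the spatial axes of a 3D or 4D array.
flipAxes <- function(x, flips) {
  nd <- length(dim(x))
  sp <- if (nd == 4L) dim(x)[-1L] else dim(x)
  idx <- lapply(seq_len(3L), function(a)
    if (flips[a]) flipIndex(sp[a]) else seq_len(sp[a]))
  if (nd == 4L) x[, idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  else x[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
}

## quantile type 7 (linear interpolation between order statistics).
linQuantile <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
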