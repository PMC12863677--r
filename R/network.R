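## The 3D U-Net: two-convolution blocks (3x3x3, group norm, ReLU) along a
## contracting path with configurable pooling (related or max), two further
## blocks at the bottleneck, a transposed-convolution expanding path with
## concatenation skips, and a 1x1x1 sigmoid head emitting per-voxel
## probabilities for the three nested tumor regions.

initBlock <- function(cin, cout) {
  list(conv1 = initConvKernel(cout, cin),
       gn1 = list(gamma = rep(1, cout), beta = rep(0, cout)),
       conv2 = initConvKernel(cout, cout),
       gn2 = list(gamma = rep(1, cout), beta = rep(0, cout)))
}

#' Build a 3D U-Net
#'
#' Instantiates the network described by `config` with He-style normal
#' weight initialization. Two builds with the same seed have identical
#' parameters.
#'
#' @param config a [NetworkConfig].
#' @param seed integer seed for weight initialization, or `NULL` to draw
#'   from the current RNG stream.
#' @return a [UNet3D].
#' @export
buildNetwork <- function(config = NetworkConfig(), seed = NULL) {
  validObject(config)
  params <- withSeed(seed, {
    L <- config@levels
    f <- config@filters
    enc <- vector("list", L)
    cin <- config@inChannels
    for (l in seq_len(L)) {
      enc[[l]] <- initBlock(cin, f[l])
      cin <- f[l]
    }
    mid <- list(initBlock(f[L], f[L + 1L]), initBlock(f[L + 1L], f[L + 1L]))
    up <- vector("list", L)
    dec <- vector("list", L)
    cin <- f[L + 1L]
    for (l in rev(seq_len(L))) {
      up[[l]] <- initConvKernel(f[l], cin)          # transposed conv to f[l]
      dec[[l]] <- initBlock(2L * f[l], f[l])        # after concat with skip
      cin <- f[l]
    }
    head <- list(W = matrix(stats::rnorm(config@outChannels * f[1L], 0,
                                         sqrt(2 / f[1L])),
                            config@outChannels, f[1L]),
                 b = numeric(config@outChannels))
    list(enc = enc, mid = mid, up = up, dec = dec, head = head)
  })
  new("UNet3D", config = config, params = params)
}

#' Number of trainable parameters
#'
#' @param network a [UNet3D].
#' @return integer parameter count.
#' @export
parameterCount <- function(network) {
  sum(vapply(flattenParams(network@params), length, integer(1)))
}

blockForward <- function(block, x, groups, train) {
  c1 <- convForward(x, block$conv1$W, block$conv1$b)
  g1 <- groupNormForward(c1, block$gn1$gamma, block$gn1$beta, groups)
  r1 <- reluForward(g1$y)
  c2 <- convForward(r1$y, block$conv2$W, block$conv2$b)
  g2 <- groupNormForward(c2, block$gn2$gamma, block$gn2$beta, groups)
  r2 <- reluForward(g2$y)
  cache <- if (train) list(x = x, g1 = g1[c("xhat", "invstd")],
                           m1 = r1$mask, h1 = r1$y,
                           g2 = g2[c("xhat", "invstd")], m2 = r2$mask)
           else NULL
  list(y = r2$y, cache = cache)
}

blockBackward <- function(block, cache, groups, dy) {
  dg2 <- reluBackward(cache$m2, dy)
  g2 <- groupNormBackward(cache$g2, block$gn2$gamma, groups, dg2)
  c2 <- convBackward(cache$h1, block$conv2$W, g2$dx)
  dg1 <- reluBackward(cache$m1, c2$dx)
  g1 <- groupNormBackward(cache$g1, block$gn1$gamma, groups, dg1)
  c1 <- convBackward(cache$x, block$conv1$W, g1$dx)
  list(dx = c1$dx,
       grads = list(conv1 = list(W = c1$dW, b = c1$db),
                    gn1 = list(gamma = g1$dgamma, beta = g1$dbeta),
                    conv2 = list(W = c2$dW, b = c2$db),
                    gn2 = list(gamma = g2$dgamma, beta = g2$dbeta)))
}

checkNetInput <- function(config, x) {
  stopIfNotRank4(x, "network input")
  if (dim(x)[1L] != config@inChannels)
    stop(sprintf("network expects %d input channels, got %d",
                 config@inChannels, dim(x)[1L]), call. = FALSE)
  div <- as.integer(2^config@levels)
  sp <- spatialDim(x)
  bad <- which(sp %% div != 0L)
  if (length(bad))
    stop(sprintf(
      "spatial axis %d (extent %d) is not divisible by %d (2^levels)",
      bad[1L], sp[bad[1L]], div), call. = FALSE)
}

#' Forward pass through a 3D U-Net
#'
#' Maps a (inChannels, D, H, W) input with spatial dims divisible by
#' `2^levels` to a (3, D, H, W) array of per-voxel probabilities in (0, 1).
#'
#' @param network a [UNet3D].
#' @param x rank-4 numeric array.
#' @param train logical; when `TRUE`, keeps the intermediate activations
#'   needed by [netBackward()] in the returned cache.
#' @return list with `y` (probabilities) and `cache` (always contains the
#'   bottleneck spatial extent and, in train mode, pooling inputs/outputs
#'   and block activations).
#' @export
netForward <- function(network, x, train = FALSE) {
  cfg <- network@config
  checkNetInput(cfg, x)
  p <- network@params
  L <- cfg@levels
  spec <- cfg@poolSpec
  skips <- vector("list", L)
  encCache <- vector("list", L)
  poolCache <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    bf <- blockForward(p$enc[[l]], h, cfg@groups, train)
    skips[[l]] <- bf$y
    encCache[[l]] <- bf$cache
    if (cfg@poolKind == "related") {
      pooled <- relatedPool3d(bf$y, spec)
      arg <- NULL
    } else {
      mp <- maxPool3dWithArg(bf$y, spec@window, spec@stride)
      pooled <- mp$y
      arg <- mp$arg
    }
    if (train) poolCache[[l]] <- list(inDim = dim(bf$y), arg = arg,
                                      x = bf$y, y = pooled)
    h <- pooled
  }
  m1 <- blockForward(p$mid[[1L]], h, cfg@groups, train)
  m2 <- blockForward(p$mid[[2L]], m1$y, cfg@groups, train)
  bottleneckDim <- spatialDim(m2$y)
  h <- m2$y
  upCache <- vector("list", L)
  decCache <- vector("list", L)
  for (l in rev(seq_len(L))) {
    ct <- convTransposeForward(h, p$up[[l]]$W, p$up[[l]]$b)
    cat_ <- abind1(ct$y, skips[[l]])
    bf <- blockForward(p$dec[[l]], cat_, cfg@groups, train)
    if (train) upCache[[l]] <- list(z = ct$z, upC = dim(ct$y)[1L])
    decCache[[l]] <- bf$cache
    h <- bf$y
  }
  logits <- conv1x1Forward(h, p$head$W, p$head$b)
  s <- sigmoidForward(logits)
  cache <- list(bottleneckDim = bottleneckDim)
  if (train)
    cache <- c(cache, list(x = x, enc = encCache, pool = poolCache,
                           mid = list(m1$cache, m2$cache), midOut1 = m1$y,
                           up = upCache, dec = decCache, headIn = h, s = s))
  list(y = s, cache = cache)
}

## concatenate two (C, D, H, W) arrays along the channel axis
abind1 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L] + db[1L], da[-1L]))
  out[seq_len(da[1L]), , , ] <- a
  out[da[1L] + seq_len(db[1L]), , , ] <- b
  out
}

#' Backward pass through a 3D U-Net
#'
#' Backpropagates the gradient of a loss with respect to the network's
#' sigmoid output through every layer and returns parameter gradients in
#' the same nested structure as `network@params`.
#'
#' @param network a [UNet3D].
#' @param cache cache from `netForward(..., train = TRUE)`.
#' @param dS gradient of the loss with respect to the output probabilities.
#' @return nested list of gradients.
#' @export
netBackward <- function(network, cache, dS) {
  cfg <- network@config
  p <- network@params
  L <- cfg@levels
  spec <- cfg@poolSpec
  grads <- list(enc = vector("list", L), mid = vector("list", 2L),
                up = vector("list", L), dec = vector("list", L))
  dlogits <- sigmoidBackward(cache$s, dS)
  hb <- conv1x1Backward(cache$headIn, p$head$W, dlogits)
  grads$head <- list(W = hb$dW, b = hb$db)
  dh <- hb$dx
  for (l in seq_len(L)) {           # decoder, shallowest first
    bb <- blockBackward(p$dec[[l]], cache$dec[[l]], cfg@groups, dh)
    grads$dec[[l]] <- bb$grads
    upC <- cache$up[[l]]$upC
    dUp <- bb$dx[seq_len(upC), , , , drop = FALSE]
    dSkip <- bb$dx[upC + seq_len(dim(bb$dx)[1L] - upC), , , , drop = FALSE]
    tb <- convTransposeBackward(cache$up[[l]]$z, p$up[[l]]$W, dUp)
    grads$up[[l]] <- list(W = tb$dW, b = tb$db)
    ## gradient flowing into the encoder skip is consumed when we reach
    ## that encoder level below
    cache$pool[[l]]$dSkip <- dSkip
    dh <- tb$dx
  }
  mb2 <- blockBackward(p$mid[[2L]], cache$mid[[2L]], cfg@groups, dh)
  grads$mid[[2L]] <- mb2$grads
  mb1 <- blockBackward(p$mid[[1L]], cache$mid[[1L]], cfg@groups, mb2$dx)
  grads$mid[[1L]] <- mb1$grads
  dh <- mb1$dx
  for (l in rev(seq_len(L))) {      # encoder, deepest first
    dPooled <- dh
    dSkipTotal <- poolBackward(dPooled, cache$pool[[l]]$inDim, spec,
                               cfg@poolKind, cache$pool[[l]]$arg) +
      cache$pool[[l]]$dSkip
    bb <- blockBackward(p$enc[[l]], cache$enc[[l]], cfg@groups, dSkipTotal)
    grads$enc[[l]] <- bb$grads
    dh <- bb$dx
  }
  grads
}

#' Number of down-sampling stages of a built network
#'
#' Confirmed by a forward-pass shape probe: the ratio of input to
#' bottleneck spatial extent is `2^levels`.
#'
#' @param network a [UNet3D].
#' @return integer.
#' @export
countDownsamplings <- function(network) {
  cfg <- network@config
  n <- as.integer(2^cfg@levels)
  x <- array(0, c(cfg@inChannels, n, n, n))
  fw <- netForward(network, x, train = FALSE)
  as.integer(round(log2(n / fw$cache$bottleneckDim[1L])))
}

## ---- parameter flattening (shared by Adam and checkpoint tests) -----------

flattenParams <- function(p, prefix = "") {
  if (is.list(p)) {
    out <- list()
    nm <- names(p)
    for (i in seq_along(p)) {
      key <- if (is.null(nm) || nm[i] == "") as.character(i) else nm[i]
      out <- c(out, flattenParams(p[[i]], paste0(prefix, "/", key)))
    }
    out
  } else {
    stats::setNames(list(p), prefix)
  }
}

## Map f over the leaves of two parallel nested lists.
mapLeaves <- function(a, b, f) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- mapLeaves(a[[i]], b[[i]], f)
    a
  } else f(a, b)
}
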