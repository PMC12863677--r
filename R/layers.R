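## Differentiable layer primitives for the 3D U-Net.
##
## Everything operates on (channel, depth, height, width) double arrays
## with batch size 1 (the training batch size of both pipelines). 3x3x3
## "same" convolutions are computed as 27 BLAS matrix products, one per
## kernel offset, which keeps memory at the size of the activations rather
## than a full im2col buffer. Backward passes are hand-derived; a finite-
## difference check in the test suite guards them.

## ---- 3x3x3 same convolution ------------------------------------------------

## Kernel offsets in (depth, height, width) raster order over {0,1,2}^3.
convOffsets <- function() windowOffsets(c(3L, 3L, 3L))

padSpatial1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L] + 2L, d[3L] + 2L, d[4L] + 2L))
  out[, 1L + seq_len(d[2L]), 1L + seq_len(d[3L]), 1L + seq_len(d[4L])] <- x
  out
}

## He-style normal initialization for a (Cout, Cin, K) kernel tensor.
initConvKernel <- function(cout, cin, k = 27L) {
  sd <- sqrt(2 / (cin * k))
  list(W = array(stats::rnorm(cout * cin * k, 0, sd), c(cout, cin, k)),
       b = numeric(cout))
}

## Forward 3x3x3 stride-1 zero-padded convolution: x (Cin,D,H,W) -> (Cout,D,H,W)
convForward <- function(x, W, b) {
  d <- dim(x)
  n <- prod(d[-1L])
  xp <- padSpatial1(x)
  off <- convOffsets()
  y <- matrix(b, nrow = dim(W)[1L], ncol = n)
  for (k in seq_len(nrow(off))) {
    xs <- xp[, off[k, 1L] + seq_len(d[2L]), off[k, 2L] + seq_len(d[3L]),
             off[k, 3L] + seq_len(d[4L]), drop = FALSE]
    dim(xs) <- c(d[1L], n)
    y <- y + W[, , k, drop = FALSE][, , 1L] %*% xs
  }
  array(y, c(dim(W)[1L], d[-1L]))
}

## Backward of convForward. Returns dx, dW, db.
convBackward <- function(x, W, dy) {
  d <- dim(x)
  n <- prod(d[-1L])
  xp <- padSpatial1(x)
  off <- convOffsets()
  dyM <- dy
  dim(dyM) <- c(dim(W)[1L], n)
  dW <- array(0, dim(W))
  db <- rowSums(dyM)
  dxp <- array(0, dim(xp))
  for (k in seq_len(nrow(off))) {
    id <- off[k, 1L] + seq_len(d[2L])
    ih <- off[k, 2L] + seq_len(d[3L])
    iw <- off[k, 3L] + seq_len(d[4L])
    xs <- xp[, id, ih, iw, drop = FALSE]
    dim(xs) <- c(d[1L], n)
    Wk <- W[, , k, drop = FALSE][, , 1L]
    dW[, , k] <- dyM %*% t(xs)
    dxk <- crossprod(Wk, dyM)            # (Cin, n)
    dxp[, id, ih, iw] <- dxp[, id, ih, iw, drop = FALSE] +
      array(dxk, c(d[1L], d[-1L]))
  }
  dx <- dxp[, 1L + seq_len(d[2L]), 1L + seq_len(d[3L]), 1L + seq_len(d[4L]),
            drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

## ---- transposed convolution (kernel 3, stride 2, exact doubling) -----------

## Implemented as zero-stuffing onto the doubled grid followed by a 3x3x3
## same convolution, which realizes a stride-2 transposed convolution with
## output size exactly 2x the input per axis.

zeroStuff2 <- function(x) {
  d <- dim(x)
  z <- array(0, c(d[1L], 2L * d[-1L]))
  z[, seq(1L, 2L * d[2L], 2L), seq(1L, 2L * d[3L], 2L),
    seq(1L, 2L * d[4L], 2L)] <- x
  z
}

convTransposeForward <- function(x, W, b) {
  z <- zeroStuff2(x)
  list(y = convForward(z, W, b), z = z)
}

convTransposeBackward <- function(z, W, dy) {
  g <- convBackward(z, W, dy)
  d <- dim(z)
  dx <- g$dx[, seq(1L, d[2L], 2L), seq(1L, d[3L], 2L), seq(1L, d[4L], 2L),
             drop = FALSE]
  list(dx = dx, dW = g$dW, db = g$db)
}

## ---- group normalization ---------------------------------------------------

## Normalizes over (channels-in-group x all voxels); gamma/beta per channel.
## Batch-size independent, which is why the architecture pairs it with
## batch size 1.
groupNormForward <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  C <- d[1L]
  gs <- C %/% groups
  xhat <- array(0, d)
  invstd <- numeric(groups)
  for (g in seq_len(groups)) {
    ch <- ((g - 1L) * gs + 1L):(g * gs)
    v <- x[ch, , , , drop = FALSE]
    mu <- mean(v)
    invstd[g] <- 1 / sqrt(mean((v - mu)^2) + eps)
    xhat[ch, , , ] <- (v - mu) * invstd[g]
  }
  y <- xhat * gamma + rep(beta, prod(d[-1L]))  # gamma/beta recycle over C
  list(y = array(y, d), xhat = xhat, invstd = invstd)
}

groupNormBackward <- function(cache, gamma, groups, dy) {
  xhat <- cache$xhat
  d <- dim(xhat)
  C <- d[1L]
  gs <- C %/% groups
  n <- prod(d[-1L])
  dyM <- dy; dim(dyM) <- c(C, n)
  xhM <- xhat; dim(xhM) <- c(C, n)
  dgamma <- rowSums(dyM * xhM)
  dbeta <- rowSums(dyM)
  dx <- array(0, d)
  dxhatM <- dyM * gamma
  for (g in seq_len(groups)) {
    ch <- ((g - 1L) * gs + 1L):(g * gs)
    m <- gs * n
    dxh <- dxhatM[ch, , drop = FALSE]
    xh <- xhM[ch, , drop = FALSE]
    s1 <- sum(dxh)
    s2 <- sum(dxh * xh)
    dxg <- cache$invstd[g] * (dxh - s1 / m - xh * (s2 / m))
    dx[ch, , , ] <- array(dxg, c(gs, d[-1L]))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- activations and 1x1x1 head -------------------------------------------

reluForward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

reluBackward <- function(mask, dy) dy * mask

## 1x1x1 convolution: pure channel mixing. W (Cout, Cin), b (Cout).
conv1x1Forward <- function(x, W, b) {
  d <- dim(x)
  n <- prod(d[-1L])
  xM <- x; dim(xM) <- c(d[1L], n)
  array(W %*% xM + b, c(nrow(W), d[-1L]))
}

conv1x1Backward <- function(x, W, dy) {
  d <- dim(x)
  n <- prod(d[-1L])
  xM <- x; dim(xM) <- c(d[1L], n)
  dyM <- dy; dim(dyM) <- c(nrow(W), n)
  list(dx = array(crossprod(W, dyM), d),
       dW = dyM %*% t(xM), db = rowSums(dyM))
}

sigmoidForward <- function(x) 1 / (1 + exp(-x))
## derivative through sigmoid given its output s: ds/dz = s (1 - s)
sigmoidBackward <- function(s, dS) dS * s * (1 - s)
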