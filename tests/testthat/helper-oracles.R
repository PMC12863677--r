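# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written in the most literal way possible (explicit loops,
# hand-rolled percentiles) so it shares no code path with the package.

# place values into a (1, d, h, w) array in (depth, height, width) raster
# order, i.e. values[1] at (1,1,1), values[2] at (1,1,2), ...
rasterWindow <- function(values, d = 2L, h = 2L, w = 2L) {
  x <- array(0, c(1L, d, h, w))
  k <- 0L
  for (dd in seq_len(d)) for (hh in seq_len(h)) for (ww in seq_len(w)) {
    k <- k + 1L
    x[1L, dd, hh, ww] <- values[k]
  }
  x
}

randVol <- function(C, d, h, w) array(stats::rnorm(C * d * h * w), c(C, d, h, w))

# hand-rolled linear-interpolation percentile (the type-7 formula written out)
oracleQuantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  hidx <- (n - 1) * p + 1
  lo <- floor(hidx)
  hi <- ceiling(hidx)
  v[lo] + (hidx - lo) * (v[hi] - v[lo])
}

# literal min-max percentile normalization of one channel vector
oracleMinmax <- function(v, pLow = 0.01, pHigh = 0.99) {
  lo <- oracleQuantile(v, pLow)
  hi <- oracleQuantile(v, pHigh)
  out <- v
  for (i in seq_along(v)) {
    x <- v[i]
    if (x < lo) x <- lo
    if (x > hi) x <- hi
    out[i] <- (x - lo) / (hi - lo)
  }
  out
}

# two-pass population mean/sd z-score of one channel vector
oracleZscore <- function(v) {
  mu <- sum(v) / length(v)
  s <- sqrt(sum((v - mu)^2) / length(v))
  (v - mu) / s
}

# exhaustive voxel-by-voxel confusion counts
oracleConfusion <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && ref[i]) tp <- tp + 1L
    else if (pred[i] && !ref[i]) fp <- fp + 1L
    else if (!pred[i] && ref[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# scalar-loop soft Dice loss (factor-2 form)
oracleDiceLoss <- function(S, R, eps = 1) {
  N <- dim(S)[1L]
  total <- 0
  for (n in seq_len(N)) {
    num <- 0; ds <- 0; dr <- 0
    s <- S[n, , , ]; r <- R[n, , , ]
    for (i in seq_along(s)) {
      num <- num + s[i] * r[i]
      ds <- ds + s[i]^2
      dr <- dr + r[i]^2
    }
    total <- total + (2 * num + eps) / (ds + dr + eps)
  }
  1 - total / N
}

# boundary voxels by explicit 6-neighbour scan (outside counts as background)
oracleBoundary <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    inside <- TRUE
    for (nb in list(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0), c(0,0,-1), c(0,0,1))) {
      ni <- i + nb[1]; nj <- j + nb[2]; nk <- k + nb[3]
      if (ni < 1 || nj < 1 || nk < 1 || ni > d[1] || nj > d[2] || nk > d[3] ||
          !mask[ni, nj, nk]) { inside <- FALSE; break }
    }
    if (!inside) out[i, j, k] <- TRUE
  }
  out
}

# all-pairs O(n^2) HD95 with explicit percentile computation
oracleHd95 <- function(pred, ref, spacing = c(1, 1, 1)) {
  A <- which(oracleBoundary(pred), arr.ind = TRUE)
  B <- which(oracleBoundary(ref), arr.ind = TRUE)
  directed <- function(P, Q) {
    dmin <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        dd <- sum(((P[i, ] - Q[j, ]) * spacing)^2)
        if (dd < best) best <- dd
      }
      dmin[i] <- sqrt(best)
    }
    oracleQuantile(dmin, 0.95)
  }
  max(directed(A, B), directed(B, A))
}

# random blob mask: union of a few balls, guaranteed non-empty
randBlob <- function(d = c(9L, 9L, 9L), nBalls = 2L) {
  m <- array(FALSE, d)
  for (b in seq_len(nBalls)) {
    c0 <- sapply(d, function(n) sample.int(n, 1))
    r <- runif(1, 1, 2.5)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      if (sum((c(i, j, k) - c0)^2) <= r^2) m[i, j, k] <- TRUE
  }
  if (!any(m)) m[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- TRUE
  m
}

# random valid BraTS label map
randLabels <- function(d = c(6L, 6L, 6L)) {
  array(sample(c(0L, 1L, 2L, 4L), prod(d), replace = TRUE,
               prob = c(0.7, 0.1, 0.15, 0.05)), d)
}

# random nested region masks
randNestedMasks <- function(d = c(6L, 6L, 6L)) {
  wt <- array(runif(prod(d)) < 0.4, d)
  tc <- wt & array(runif(prod(d)) < 0.5, d)
  et <- tc & array(runif(prod(d)) < 0.5, d)
  RegionMasks(et = et, tc = tc, wt = wt)
}

tinyNetConfig <- function(poolKind = "related") {
  NetworkConfig(filters = c(4L, 8L, 16L, 32L), groups = 4L,
                poolKind = poolKind)
}
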