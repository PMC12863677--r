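# Normalization, brain cropping, padding and random patch extraction.

# local helper: spatial dims of a rank-4 array
spatialDimTest <- function(x) dim(x)[-1L]

test_that("min-max normalization maps non-zero voxels into [0,1], zeros stay zero", {
  set.seed(1)
  x <- array(0, c(2, 6, 6, 6))
  x[1, 2:5, 2:5, 2:5] <- rlnorm(64)
  x[2, 1:4, 1:4, 1:4] <- runif(64, 10, 500)
  y <- minmaxNormalize(x)
  for (c in 1:2) {
    nz <- x[c, , , ] != 0
    expect_true(all(y[c, , , ][nz] >= 0 & y[c, , , ][nz] <= 1))
    expect_true(all(y[c, , , ][!nz] == 0))
  }
})

test_that("min-max matches the sort-clip-rescale oracle on a uniform grid", {
  x <- array(0, c(1, 10, 10, 10))
  x[1, , , ] <- as.numeric(1:1000)
  y <- minmaxNormalize(x)
  expect_equal(as.vector(y[1, , , ]), oracleMinmax(as.numeric(1:1000)),
               tolerance = 1e-6)
})

test_that("degenerate channels are handled with warnings", {
  x <- array(0, c(1, 4, 4, 4))
  x[1, 1:2, 1, 1] <- 5                        # all non-zero values equal
  expect_warning(y <- minmaxNormalize(x), "degenerate")
  expect_true(all(y == 0))
  z <- array(0, c(1, 4, 4, 4))                # entirely zero channel
  expect_warning(y2 <- minmaxNormalize(z), "entirely zero")
  expect_identical(y2, z)
  expect_warning(y3 <- zscoreNormalize(z), "entirely zero")
  expect_identical(y3, z)
})

test_that("z-score maps {2,4} to {-1,+1} and achieves mean 0 / population sd 1", {
  x <- array(0, c(1, 4, 4, 4))
  x[1, 1, 1, 1] <- 2
  x[1, 2, 1, 1] <- 4
  y <- zscoreNormalize(x)
  expect_equal(sort(y[1, , , ][x[1, , , ] != 0]), c(-1, 1))
  set.seed(2)
  x2 <- array(0, c(1, 8, 8, 8))
  sel <- runif(512) < 0.6
  x2[1, , , ][sel] <- rlnorm(sum(sel), 1, 0.5)
  y2 <- zscoreNormalize(x2)
  v <- y2[1, , , ][x2[1, , , ] != 0]
  expect_lt(abs(mean(v)), 1e-6)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
  expect_true(all(y2[1, , , ][x2[1, , , ] == 0] == 0))
  # naive two-pass oracle, elementwise
  expect_equal(v, oracleZscore(x2[1, , , ][x2[1, , , ] != 0]),
               tolerance = 1e-6)
})

test_that("cropToBrain finds the exact support box and restores exactly", {
  x <- array(0, c(2, 24, 20, 16))
  x[1, 11:20, 6:15, 1:8] <- 1                 # support only here
  cr <- cropToBrain(x)
  expect_identical(cr$crop$start, c(11L, 6L, 1L))
  expect_identical(cr$crop$stop, c(20L, 15L, 8L))
  expect_identical(dim(cr$image), c(2L, 10L, 10L, 8L))
  expect_identical(uncrop(cr$image, cr$crop), x)
  full <- array(1, c(1, 4, 4, 4))
  expect_identical(cropToBrain(full)$image, full)
  expect_error(cropToBrain(array(0, c(1, 4, 4, 4))), "entirely zero")
})

test_that("cropToBrain box equals the brute-force coordinate scan on sparse images", {
  set.seed(3)
  for (i in 1:10) {
    x <- array(0, c(2, 9, 9, 9))
    n <- sample(3:10, 1)
    for (j in seq_len(n))
      x[sample(1:2, 1), sample(9, 1), sample(9, 1), sample(9, 1)] <- runif(1)
    coords <- which(apply(x != 0, c(2, 3, 4), any), arr.ind = TRUE)
    cr <- cropToBrain(x)
    expect_identical(cr$crop$start, as.integer(apply(coords, 2, min)))
    expect_identical(cr$crop$stop, as.integer(apply(coords, 2, max)))
  }
})

test_that("padToMultiple achieves divisibility minimally and round-trips", {
  x <- array(stats::rnorm(1 * 13 * 8 * 21), c(1, 13, 8, 21))
  pd <- padToMultiple(x, 8L)
  expect_identical(spatialDimTest(pd$image), c(16L, 8L, 24L))
  expect_identical(unpad(pd$image, pd$pad), x)
  # already divisible: identity
  y <- array(1, c(1, 16, 16, 16))
  pdy <- padToMultiple(y, 8L)
  expect_identical(pdy$image, y)
  # padding is balanced with the extra voxel trailing
  expect_true(all(pd$pad$after - pd$pad$before %in% c(0L, 1L)))
})

test_that("randomCrop is identity at matching size and deterministic under a seed", {
  x <- randVol(2, 8, 8, 8)
  lab <- randLabels(c(8L, 8L, 8L))
  p <- randomCrop(x, lab, c(8L, 8L, 8L))
  expect_identical(p$image, x)
  expect_identical(p$labels, lab)
  set.seed(77)
  a <- randomCrop(x, lab, c(4L, 4L, 4L))
  set.seed(77)
  b <- randomCrop(x, lab, c(4L, 4L, 4L))
  expect_identical(a, b)
  # alignment: the label patch is the same window as the image patch
  xc <- array(seq_len(8^3), c(1, 8, 8, 8))
  lc <- array(seq_len(8^3), c(8, 8, 8))
  set.seed(5)
  pc <- randomCrop(xc, lc, c(3L, 3L, 3L))
  expect_identical(as.vector(pc$image[1, , , ]), as.vector(pc$labels))
})

test_that("smaller inputs are zero-padded up to the patch size, centered", {
  x <- randVol(1, 4, 8, 8)
  p <- randomCrop(x, NULL, c(8L, 8L, 8L))
  expect_identical(dim(p$image), c(1L, 8L, 8L, 8L))
  expect_identical(p$image[, 3:6, , , drop = FALSE], x)
  expect_true(all(p$image[, c(1:2, 7:8), , ] == 0))
})

test_that("random crop offsets are uniform over the valid range", {
  # 10,000 draws of a 4^3 patch from a 8^3 volume: offsets uniform on {0..4}^3
  x <- array(0, c(1, 8, 8, 8))
  set.seed(123)
  draws <- t(replicate(10000, randomCrop(x, NULL, c(4L, 4L, 4L))$offset))
  for (a in 1:3) {
    tab <- table(factor(draws[, a], levels = 0:4))
    p <- stats::chisq.test(tab)$p.value
    expect_gt(p, 0.01)
  }
})
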