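# Augmentation semantics: identity at probability zero, determinism under a
# seed, label safety, and the stated event rates/distributions.

test_that("an all-zero policy is the identity", {
  set.seed(1)
  x <- randVol(4, 4, 4, 4)
  lab <- randLabels(c(4L, 4L, 4L))
  out <- applyAugmentations(x, lab, AugmentationPolicy())
  expect_identical(out$image, x)
  expect_identical(out$labels, lab)
})

test_that("forced flips are involutions restoring the original", {
  set.seed(2)
  x <- randVol(2, 4, 6, 8)
  lab <- randLabels(c(4L, 6L, 8L))
  f1 <- randomFlips(x, lab, p = 1)
  expect_true(all(f1$flips))
  f2 <- randomFlips(f1$image, f1$labels, p = 1)
  expect_identical(f2$image, x)
  expect_identical(f2$labels, lab)
})

test_that("flips move image and labels by the identical permutation", {
  # coordinate-encoded phantom: voxel value equals its linear index
  x <- array(seq_len(4^3), c(1, 4, 4, 4))
  lab <- array(seq_len(4^3) %% 2L, c(4, 4, 4)) * 4L  # labels in {0,4}
  set.seed(3)
  out <- randomFlips(x, lab, p = 1)
  # wherever the image voxel moved, the label voxel moved with it
  perm <- match(as.vector(out$image[1, , , ]), as.vector(x[1, , , ]))
  expect_identical(as.vector(out$labels), as.vector(lab)[perm])
})

test_that("intensity augmentations never alter the labels", {
  set.seed(4)
  x <- randVol(4, 4, 4, 4)
  lab <- randLabels(c(4L, 4L, 4L))
  pol <- AugmentationPolicy(pRescale = 1, pOffset = 1, pNoise = 1,
                            noiseSigma = 0.2, pChannelDrop = 1, pFlip = 0)
  out <- applyAugmentations(x, lab, pol)
  expect_identical(out$labels, lab)
  expect_false(identical(out$image, x))
})

test_that("a fixed seed reproduces the augmented sample bit for bit", {
  x <- randVol(4, 4, 4, 4)
  lab <- randLabels(c(4L, 4L, 4L))
  pol <- pipelinePolicy("A")
  set.seed(99); a <- applyAugmentations(x, lab, pol)
  set.seed(99); b <- applyAugmentations(x, lab, pol)
  expect_identical(a, b)
})

test_that("channel dropping zeroes exactly one channel at p = 1 and none at p = 0", {
  set.seed(5)
  x <- randVol(4, 3, 3, 3)
  y <- dropChannel(x, p = 1)
  zeroed <- vapply(1:4, function(c) all(y[c, , , ] == 0), logical(1))
  expect_identical(sum(zeroed), 1L)
  expect_identical(dropChannel(x, p = 0), x)
  expect_error(dropChannel(randVol(1, 2, 2, 2), p = 1), "2 channels")
})

test_that("channel-drop events occur at the pipeline-A rate of 16%", {
  x <- randVol(4, 2, 2, 2)
  x <- x + 10                                  # keep all voxels non-zero
  set.seed(6)
  n <- 10000
  hits <- logical(n)
  for (i in seq_len(n)) {
    y <- dropChannel(x, p = 0.16)
    hits[i] <- any(vapply(1:4, function(c) all(y[c, , , ] == 0), logical(1)))
  }
  p0 <- 0.16
  expect_lt(abs(mean(hits) - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("the dropped channel is chosen uniformly", {
  x <- randVol(4, 2, 2, 2) + 10
  set.seed(7)
  n <- 10000
  which_ <- integer(n)
  for (i in seq_len(n)) {
    y <- dropChannel(x, p = 1)
    which_[i] <- which(vapply(1:4, function(c) all(y[c, , , ] == 0), logical(1)))
  }
  counts <- tabulate(which_, 4)
  # each channel within 3 sigma of n/4 under the multinomial
  expect_true(all(abs(counts - n / 4) < 3 * sqrt(n * 0.25 * 0.75)))
})

test_that("rescale factors are uniform on [0.9, 1.1] (KS test)", {
  x <- array(1, c(1, 2, 2, 2))                 # factor is read off the output
  set.seed(8)
  factors <- replicate(10000, channelRescale(x, p = 1)[1, 1, 1, 1])
  ks <- stats::ks.test(factors, "punif", 0.9, 1.1)
  expect_gt(ks$p.value, 0.01)
  expect_true(all(factors >= 0.9 & factors <= 1.1))
})

test_that("per-axis flip events occur at the configured pipeline rates", {
  x <- array(seq_len(2^3), c(1, 2, 2, 2))
  set.seed(9)
  n <- 10000
  for (p0 in c(0.8, 0.5)) {
    flips <- replicate(n, randomFlips(x, NULL, p = p0)$flips[1])
    expect_lt(abs(mean(flips) - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("a forced rescale factor scales every voxel exactly", {
  x <- randVol(1, 3, 3, 3)
  y <- channelRescale(x, p = 1, range = c(1.1, 1.1))
  expect_equal(y, x * 1.1, tolerance = 1e-12)
  z <- channelOffset(x, p = 1, range = c(0.07, 0.07))
  expect_equal(z, x + 0.07, tolerance = 1e-12)
})
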