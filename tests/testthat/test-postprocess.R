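# Label algebra, thresholding, ensembling and full-volume inference.

test_that("regionsFromLabels implements the BraTS region unions", {
  lab <- array(0L, c(3, 3, 3))
  expect_true(all(!regionMask(regionsFromLabels(lab), "WT")))
  lab[2, 2, 2] <- 4L
  m <- regionsFromLabels(lab)
  expect_true(m@et[2, 2, 2] && m@tc[2, 2, 2] && m@wt[2, 2, 2])
  expect_identical(sum(m@et), 1L)
  lab2 <- array(c(0L, 1L, 2L, 4L), c(4, 1, 1))
  m2 <- regionsFromLabels(lab2)
  expect_identical(as.vector(m2@et), c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(as.vector(m2@tc), c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(as.vector(m2@wt), c(FALSE, TRUE, TRUE, TRUE))
  bad <- array(3L, c(2, 2, 2))
  expect_error(regionsFromLabels(bad), "3")
})

test_that("reconstructLabels inverts regionsFromLabels on random label maps", {
  set.seed(1)
  for (i in 1:100) {
    lab <- randLabels()
    m <- regionsFromLabels(lab)
    back <- labelArray(reconstructLabels(m))
    expect_identical(back, lab)
    # voxel count conservation
    expect_identical(sum(regionMask(m, "WT")),
                     sum(lab == 1L) + sum(lab == 2L) + sum(lab == 4L))
  }
})

test_that("regionsFromLabels inverts reconstructLabels on nested masks", {
  set.seed(2)
  for (i in 1:100) {
    m <- randNestedMasks()
    lab <- reconstructLabels(m)
    m2 <- regionsFromLabels(lab)
    expect_identical(m2@et, m@et)
    expect_identical(m2@tc, m@tc)
    expect_identical(m2@wt, m@wt)
  }
})

test_that("concentric boxes reconstruct to annular label shells", {
  et <- tc <- wt <- array(FALSE, c(9, 9, 9))
  wt[2:8, 2:8, 2:8] <- TRUE
  tc[3:7, 3:7, 3:7] <- TRUE
  et[4:6, 4:6, 4:6] <- TRUE
  lab <- labelArray(reconstructLabels(RegionMasks(et, tc, wt)))
  expect_true(all(lab[4:6, 4:6, 4:6] == 4L))
  expect_identical(sum(lab == 4L), 27L)
  expect_identical(sum(lab == 1L), 125L - 27L)       # TC shell
  expect_identical(sum(lab == 2L), 343L - 125L)      # edema shell
  expect_identical(sum(lab == 0L), 729L - 343L)
})

test_that("non-nested masks are rejected", {
  et <- array(TRUE, c(2, 2, 2))
  tc <- array(FALSE, c(2, 2, 2))
  wt <- array(TRUE, c(2, 2, 2))
  expect_error(reconstructLabels(RegionMasks(et, tc, wt)), "nested")
})

test_that("binarize applies the >= tau rule and enforces nesting", {
  p <- array(0.6, c(3, 2, 2, 2))
  m <- binarize(p)
  expect_true(all(m@et) && all(m@tc) && all(m@wt))
  # exact threshold value is positive
  p2 <- array(0.5, c(3, 2, 2, 2))
  expect_true(all(binarize(p2)@et))
  set.seed(3)
  for (i in 1:100) {
    pr <- array(runif(3 * 4^3), c(3, 4, 4, 4))
    expect_true(isNested(binarize(pr)))
  }
})

test_that("ensemble averaging is idempotent, exact and order invariant", {
  set.seed(4)
  m <- array(runif(3 * 4^3), c(3, 4, 4, 4))
  expect_equal(ensembleAverage(list(m, m, m)), m)
  zero <- array(0, dim(m)); one <- array(1, dim(m))
  expect_equal(ensembleAverage(list(zero, one)), array(0.5, dim(m)))
  maps <- lapply(1:8, function(i) array(runif(3 * 4^3), c(3, 4, 4, 4)))
  avg <- ensembleAverage(maps)
  # loop oracle
  acc <- array(0, dim(m))
  for (mm in maps) acc <- acc + mm
  expect_lt(max(abs(avg - acc / 8)), 1e-6)
  perm <- ensembleAverage(maps[sample(8)])
  expect_equal(perm, avg, tolerance = 1e-12)
  expect_error(ensembleAverage(list()), "non-empty")
  expect_error(ensembleAverage(list(m, array(0, c(3, 2, 2, 2)))), "shape")
})

test_that("predictCase restores probabilities onto the input grid", {
  ph <- generatePhantom(PhantomSpec(shape = c(20L, 18L, 22L), seed = 5L))
  net <- buildNetwork(tinyNetConfig(), seed = 6)
  cfg <- pipelineConfig("A", network = tinyNetConfig())
  probs <- predictCase(net, ph$image, cfg)
  expect_identical(dim(probs), c(3L, 20L, 18L, 22L))
  expect_true(all(probs >= 0 & probs <= 1))
  # outside the brain crop the probability is exactly zero
  corner <- probs[, 1, 1, 1]
  expect_identical(as.numeric(corner), c(0, 0, 0))
  # determinism
  probs2 <- predictCase(net, ph$image, cfg)
  expect_identical(probs, probs2)
})

test_that("pre-padded and unpadded inputs give identical restored maps", {
  ph <- generatePhantom(PhantomSpec(shape = c(16L, 16L, 16L), seed = 7L))
  net <- buildNetwork(tinyNetConfig(), seed = 8)
  cfg <- pipelineConfig("A", network = tinyNetConfig())
  probs <- predictCase(net, ph$image, cfg)
  # embed the same case into a larger zero volume: the restored map over
  # the embedded region must be identical (inference crops to the brain)
  big <- array(0, c(4, 24, 24, 24))
  big[, 5:20, 5:20, 5:20] <- volArray(ph$image)
  probsBig <- predictCase(net, big, cfg)
  expect_equal(probsBig[, 5:20, 5:20, 5:20], probs, tolerance = 1e-12)
  expect_true(all(probsBig[, 1:4, , ] == 0))
})
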