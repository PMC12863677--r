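# Architecture contracts of the 3D U-Net: shapes, seeding, pooling
# interchangeability, layer/function agreement, and backprop correctness.

test_that("forward pass preserves spatial shape and outputs probabilities", {
  net <- buildNetwork(tinyNetConfig(), seed = 1)
  x <- randVol(4, 16, 16, 16)
  fw <- netForward(net, x)
  expect_identical(dim(fw$y), c(3L, 16L, 16L, 16L))
  expect_true(all(fw$y > 0 & fw$y < 1))
  # non-cubic input
  x2 <- randVol(4, 8, 16, 24)
  expect_identical(dim(netForward(net, x2)$y), c(3L, 8L, 16L, 24L))
})

test_that("full BraTS-resolution input maps (4,128,128,128) to (3,128,128,128)", {
  cfg <- NetworkConfig(filters = c(8L, 16L, 32L, 64L), groups = 8L)
  net <- buildNetwork(cfg, seed = 2)
  x <- array(stats::rnorm(4 * 128^3, 0.3, 0.2), c(4, 128, 128, 128))
  fw <- netForward(net, x)
  expect_identical(dim(fw$y), c(3L, 128L, 128L, 128L))
  expect_true(all(fw$y > 0 & fw$y < 1))
})

test_that("indivisible spatial dims are rejected before any computation", {
  net <- buildNetwork(tinyNetConfig(), seed = 1)
  expect_error(netForward(net, randVol(4, 12, 16, 16)), "divisible by 8")
  expect_error(netForward(net, randVol(2, 16, 16, 16)), "input channels")
})

test_that("identical seeds build identical parameter tensors", {
  a <- buildNetwork(tinyNetConfig(), seed = 7)
  b <- buildNetwork(tinyNetConfig(), seed = 7)
  expect_identical(a@params, b@params)
  c_ <- buildNetwork(tinyNetConfig(), seed = 8)
  expect_false(identical(a@params, c_@params))
})

test_that("related and max pooling builds have identical parameter counts", {
  a <- buildNetwork(tinyNetConfig("related"), seed = 1)
  b <- buildNetwork(tinyNetConfig("max"), seed = 1)
  expect_identical(parameterCount(a), parameterCount(b))
})

test_that("countDownsamplings equals levels and the bottleneck shrinks by 2^levels", {
  net3 <- buildNetwork(tinyNetConfig(), seed = 1)
  expect_identical(countDownsamplings(net3), 3L)
  cfg2 <- NetworkConfig(filters = c(4L, 8L, 16L), groups = 4L, levels = 2L)
  net2 <- buildNetwork(cfg2, seed = 1)
  expect_identical(countDownsamplings(net2), 2L)
  # shape probe: input 16 -> bottleneck 16 / 2^3 = 2
  fw <- netForward(net3, randVol(4, 16, 16, 16))
  expect_identical(fw$cache$bottleneckDim[1L], 2L)
})

test_that("the pooling layer agrees with the array-level operator", {
  for (kind in c("related", "max")) {
    net <- buildNetwork(tinyNetConfig(kind), seed = 3)
    x <- randVol(4, 8, 8, 8)
    fw <- netForward(net, x, train = TRUE)
    for (l in 1:3) {
      pre <- fw$cache$pool[[l]]$x
      post <- fw$cache$pool[[l]]$y
      ref <- if (kind == "related") relatedPool3d(pre, net@config@poolSpec)
             else maxPool3d(pre)
      expect_lt(max(abs(post - ref)), 1e-6)
    }
  }
})

test_that("network gradients match finite differences across layer types", {
  set.seed(11)
  net <- buildNetwork(tinyNetConfig(), seed = 5)
  x <- randVol(4, 8, 8, 8)
  R <- array(as.numeric(rbinom(3 * 8^3, 1, 0.3)), c(3, 8, 8, 8))
  fw <- netForward(net, x, train = TRUE)
  grads <- netBackward(net, fw$cache, diceLossGrad(fw$y, R))
  lossOf <- function(p) {
    n <- net; n@params <- p
    diceLoss(netForward(n, x)$y, R)
  }
  setLeaf <- function(lst, keys, idx, d) {
    if (length(keys) == 0L) { lst[idx] <- lst[idx] + d; return(lst) }
    lst[[keys[[1L]]]] <- setLeaf(lst[[keys[[1L]]]], keys[-1L], idx, d)
    lst
  }
  paths <- list(list("enc", 1L, "conv1", "W"), list("enc", 2L, "gn1", "gamma"),
                list("enc", 3L, "conv2", "b"), list("mid", 1L, "conv1", "W"),
                list("mid", 2L, "gn2", "beta"), list("up", 2L, "W"),
                list("up", 3L, "b"), list("dec", 1L, "conv2", "W"),
                list("head", "W"), list("head", "b"))
  eps <- 1e-5
  for (pth in paths) {
    g <- grads; leaf <- net@params
    for (k in pth) { g <- g[[k]]; leaf <- leaf[[k]] }
    # probe the entry of largest gradient magnitude (avoids dead-ReLU zeros)
    i <- which.max(abs(g))
    fd <- (lossOf(setLeaf(net@params, pth, i, eps)) -
           lossOf(setLeaf(net@params, pth, i, -eps))) / (2 * eps)
    expect_lt(abs(g[i] - fd), 1e-4 * max(1, abs(fd)))
  }
})

test_that("max-pooling backward routes gradient only to window maxima", {
  set.seed(12)
  x <- randVol(1, 4, 4, 4)
  mp <- RelPoolSeg:::maxPool3dWithArg(x)
  dy <- array(1, c(1, 2, 2, 2))
  dx <- RelPoolSeg:::poolBackward(dy, dim(x), PoolingSpec(), "max", mp$arg)
  expect_equal(sum(dx != 0), 8)              # one voxel per window
  expect_equal(sum(dx), 8)
  # the non-zero voxels are exactly the window maxima
  expect_equal(sort(x[dx != 0]), sort(as.vector(mp$y)))
})
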