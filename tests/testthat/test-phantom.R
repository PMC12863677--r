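# Phantom generator: geometry, determinism, label validity, NIfTI layout.

test_that("a noiseless phantom equals its tissue contrast table exactly", {
  spec <- PhantomSpec(shape = c(16L, 16L, 16L), noiseSigma = 0, seed = 1L)
  ph <- generatePhantom(spec)
  x <- volArray(ph$image)
  lab <- labelArray(ph$labels)
  brain <- apply(x != 0, c(2, 3, 4), any)
  contrast <- spec@contrast
  tissueCol <- c(`0` = 1L, `2` = 2L, `1` = 3L, `4` = 4L)
  for (m in 1:4) {
    ch <- x[m, , , ]
    for (lv in c(0L, 1L, 2L, 4L)) {
      sel <- brain & lab == lv
      if (any(sel))
        expect_true(all(ch[sel] == contrast[m, tissueCol[[as.character(lv)]]]))
    }
    expect_true(all(ch[!brain] == 0))
  }
})

test_that("the same seed regenerates the identical case", {
  spec <- PhantomSpec(seed = 42L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(volArray(a$image), volArray(b$image))
  expect_identical(labelArray(a$labels), labelArray(b$labels))
})

test_that("nesting violations in the spec are rejected", {
  expect_error(PhantomSpec(regionRadii = rbind(wt = c(3, 3, 3),
                                               tc = c(4, 4, 4),
                                               et = c(1, 1, 1))),
               "nested")
})

test_that("the enhancing-core voxel count approximates the ellipsoid volume", {
  # radius >= 8 voxels: voxelized volume within 5% of (4/3) pi a b c
  spec <- PhantomSpec(shape = c(40L, 40L, 40L),
                      brainRadii = c(19, 19, 19),
                      tumorCenter = c(20.5, 20.5, 20.5),
                      regionRadii = rbind(wt = c(13, 12.5, 13.5),
                                          tc = c(11, 10.5, 11.5),
                                          et = c(9, 8, 8.5)),
                      noiseSigma = 0, seed = 2L)
  ph <- generatePhantom(spec)
  count <- sum(labelArray(ph$labels) == 4L)
  analytic <- 4 / 3 * pi * prod(spec@regionRadii[3L, ])
  expect_lt(abs(count - analytic) / analytic, 0.05)
})

test_that("every phantom label map passes the region algebra and is nested", {
  set.seed(3)
  for (i in 1:5) {
    ph <- generatePhantom(PhantomSpec(seed = i))
    m <- regionsFromLabels(ph$labels)
    expect_true(isNested(m))
  }
})

test_that("cropToBrain recovers the brain ellipsoid bounding box within 1 voxel", {
  spec <- PhantomSpec(shape = c(32L, 32L, 32L), seed = 4L)
  ph <- generatePhantom(spec)
  cr <- cropToBrain(volArray(ph$image))
  center <- (spec@shape + 1) / 2
  for (a in 1:3) {
    lo <- ceiling(center[a] - spec@brainRadii[a])
    hi <- floor(center[a] + spec@brainRadii[a])
    expect_lte(abs(cr$crop$start[a] - lo), 1)
    expect_lte(abs(cr$crop$stop[a] - hi), 1)
  }
})

test_that("generateDataset writes complete BraTS-layout cases and a manifest", {
  dir <- withr::local_tempdir()
  ids <- generateDataset(3, dir, PhantomSpec(shape = c(12L, 12L, 12L)),
                         seed = 5L)
  expect_length(ids, 3L)
  for (id in ids) {
    files <- sprintf("%s_%s.nii.gz", id, c("t1", "t1ce", "t2", "flair", "seg"))
    expect_true(all(file.exists(file.path(dir, id, files))))
  }
  expect_identical(listCases(dir), sort(ids))
  # round trip through NIfTI
  case <- readCase(file.path(dir, ids[1]))
  expect_s4_class(case$image, "MultiModalVolume")
  expect_identical(dim(volArray(case$image)), c(4L, 12L, 12L, 12L))
  expect_true(all(labelArray(case$labels) %in% c(0L, 1L, 2L, 4L)))
  # manifest regenerates the cases (bit-identical in memory; the stored
  # intensities round-trip through NIfTI at double precision)
  regen <- regenerateFromManifest(file.path(dir, "manifest.json"))
  regen2 <- regenerateFromManifest(file.path(dir, "manifest.json"))
  expect_identical(volArray(regen[[ids[1]]]$image),
                   volArray(regen2[[ids[1]]]$image))
  expect_equal(volArray(regen[[ids[1]]]$image), volArray(case$image),
               tolerance = 1e-12)
  expect_identical(labelArray(regen[[ids[2]]]$labels),
                   labelArray(readCase(file.path(dir, ids[2]))$labels))
})

test_that("label histograms across jittered cases contain all four classes", {
  dir <- withr::local_tempdir()
  generateDataset(20, dir, PhantomSpec(shape = c(16L, 16L, 16L)), seed = 6L)
  seen <- integer(0)
  for (id in listCases(dir)) {
    lab <- labelArray(readCase(file.path(dir, id))$labels)
    seen <- union(seen, unique(as.vector(lab)))
  }
  expect_setequal(seen, c(0L, 1L, 2L, 4L))
})
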