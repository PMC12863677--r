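## Synthetic BraTS-like phantom cases: a brain ellipsoid of non-zero
## intensity on a zero background containing nested tumor ellipsoids with
## modality-dependent contrast and additive Gaussian noise. The phantoms
## exercise every stage of the pipeline (normalization, cropping, the
## network, the label algebra, training) with known ground truth and no
## dataset download; they emulate the geometry and label conventions of
## real cases, not MRI physics.

#' Default modality-by-tissue contrast table
#'
#' Mean intensities per (modality, tissue). Qualitatively BraTS-like:
#' enhancing tumor is brightest in post-contrast T1 and edema is brightest
#' in FLAIR. The exact values are fixture constants.
#'
#' @return 4x4 numeric matrix, rows t1/t1ce/t2/flair, columns
#'   brain/edema/ncr/et.
#' @export
defaultContrast <- function() {
  m <- rbind(
    t1    = c(brain = 0.50, edema = 0.35, ncr = 0.25, et = 0.45),
    t1ce  = c(brain = 0.45, edema = 0.40, ncr = 0.30, et = 0.95),
    t2    = c(brain = 0.40, edema = 0.70, ncr = 0.60, et = 0.50),
    flair = c(brain = 0.35, edema = 0.90, ncr = 0.50, et = 0.55))
  m
}

#' Construct a phantom specification
#'
#' @param shape integer spatial extent (depth, height, width).
#' @param brainRadii numeric brain ellipsoid semi-axes (voxels); default
#'   just under half the extent.
#' @param tumorCenter numeric tumor center; default slightly off the brain
#'   center.
#' @param regionRadii 3x3 matrix of semi-axes, rows WT, TC, ET (strictly
#'   nested); default proportional to the volume size.
#' @param contrast 4x4 modality-by-tissue mean intensity matrix.
#' @param noiseSigma additive Gaussian noise level (intensities are clipped
#'   below at a small positive floor inside the brain).
#' @param seed integer RNG seed.
#' @return a [PhantomSpec].
#' @export
PhantomSpec <- function(shape = c(32L, 32L, 32L),
                        brainRadii = (shape - 2) / 2.2,
                        tumorCenter = (shape + 1) / 2 + shape / 16,
                        regionRadii = rbind(wt = shape / 4.5,
                                            tc = shape / 6.5,
                                            et = shape / 10),
                        contrast = defaultContrast(),
                        noiseSigma = 0.05, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape),
      brainRadii = as.numeric(brainRadii),
      tumorCenter = as.numeric(tumorCenter),
      regionRadii = unname(as.matrix(regionRadii)), contrast = unname(contrast),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

## logical ellipsoid mask ((x-c)/r)^2 summed <= 1 on a voxel grid
ellipsoidMask <- function(shape, center, radii) {
  d <- seq_len(shape[1L])
  h <- seq_len(shape[2L])
  w <- seq_len(shape[3L])
  dd <- ((d - center[1L]) / radii[1L])^2
  hh <- ((h - center[2L]) / radii[2L])^2
  ww <- ((w - center[3L]) / radii[3L])^2
  outer(outer(dd, hh, `+`), ww, `+`) <= 1
}

#' Generate one phantom case
#'
#' Builds the label map (edema shell label 2, NCR/NET shell label 1,
#' enhancing core label 4, all inside a brain ellipsoid) and the 4-modality
#' intensity volume: per-tissue means from the contrast table plus Gaussian
#' noise, clipped below at a small positive floor inside the brain so the
#' non-zero support is exactly the brain ellipsoid; the background is
#' exactly zero. Deterministic given `spec@seed`.
#'
#' @param spec a [PhantomSpec].
#' @return list with `image` ([MultiModalVolume]) and `labels` ([LabelMap]).
#' @export
generatePhantom <- function(spec = PhantomSpec()) {
  validObject(spec)
  shape <- spec@shape
  center <- (shape + 1) / 2
  brain <- ellipsoidMask(shape, center, spec@brainRadii)
  wt <- ellipsoidMask(shape, spec@tumorCenter, spec@regionRadii[1L, ]) & brain
  tc <- ellipsoidMask(shape, spec@tumorCenter, spec@regionRadii[2L, ]) & brain
  et <- ellipsoidMask(shape, spec@tumorCenter, spec@regionRadii[3L, ]) & brain
  lab <- array(0L, shape)
  lab[wt] <- 2L
  lab[tc] <- 1L
  lab[et] <- 4L
  tissue <- array(1L, shape)            # 1 brain, 2 edema, 3 ncr, 4 et
  tissue[lab == 2L] <- 2L
  tissue[lab == 1L] <- 3L
  tissue[lab == 4L] <- 4L
  img <- withSeed(spec@seed, {
    x <- array(0, c(4L, shape))
    nBrain <- sum(brain)
    for (m in 1:4) {
      vals <- spec@contrast[m, tissue[brain]]
      if (spec@noiseSigma > 0)
        vals <- vals + stats::rnorm(nBrain, 0, spec@noiseSigma)
      ch <- array(0, shape)
      ch[brain] <- pmax(vals, 0.01)     # keep the brain support non-zero
      x[m, , , ] <- ch
    }
    x
  })
  list(image = MultiModalVolume(img), labels = LabelMap(lab))
}

#' Generate a BraTS-layout phantom dataset on disk
#'
#' Writes `nCases` case directories `<case>/<case>_{t1,t1ce,t2,flair,seg}.nii.gz`
#' with jittered tumor centers, radii and contrasts, plus a JSON manifest
#' recording every specification so that the dataset can be regenerated
#' bit-identically.
#'
#' @param nCases number of cases (>= 1).
#' @param dir output directory.
#' @param baseSpec the [PhantomSpec] to jitter around.
#' @param seed integer seed driving the jitter and every per-case seed.
#' @param jitter list with `center` (voxels), `radiiFrac` and
#'   `contrastFrac` (relative), the uniform jitter half-widths.
#' @return character vector of case ids, invisibly.
#' @export
generateDataset <- function(nCases, dir, baseSpec = PhantomSpec(), seed = 1L,
                            jitter = list(center = 1.5, radiiFrac = 0.12,
                                          contrastFrac = 0.08)) {
  stopifnot(nCases >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- withSeed(seed, lapply(seq_len(nCases), function(i) {
    ctr <- baseSpec@tumorCenter + stats::runif(3, -1, 1) * jitter$center
    rad <- baseSpec@regionRadii *
      (1 + stats::runif(3, -1, 1) * jitter$radiiFrac)
    con <- baseSpec@contrast *
      (1 + array(stats::runif(16, -1, 1) * jitter$contrastFrac, c(4, 4)))
    PhantomSpec(shape = baseSpec@shape, brainRadii = baseSpec@brainRadii,
                tumorCenter = ctr, regionRadii = rad, contrast = con,
                noiseSigma = baseSpec@noiseSigma,
                seed = childSeed(seed, i))
  }))
  ids <- sprintf("phantom_%03d", seq_len(nCases))
  for (i in seq_len(nCases)) {
    case <- generatePhantom(specs[[i]])
    writeCase(case$image, case$labels, file.path(dir, ids[i]), ids[i])
  }
  manifest <- lapply(seq_len(nCases), function(i) specToList(specs[[i]]))
  names(manifest) <- ids
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ids)
}

specToList <- function(spec) {
  list(shape = spec@shape, brainRadii = spec@brainRadii,
       tumorCenter = spec@tumorCenter,
       regionRadii = as.vector(t(spec@regionRadii)),
       contrast = as.vector(t(spec@contrast)),
       noiseSigma = spec@noiseSigma, seed = spec@seed)
}

specFromList <- function(x) {
  PhantomSpec(shape = unlist(x$shape), brainRadii = unlist(x$brainRadii),
              tumorCenter = unlist(x$tumorCenter),
              regionRadii = matrix(unlist(x$regionRadii), 3, 3, byrow = TRUE),
              contrast = matrix(unlist(x$contrast), 4, 4, byrow = TRUE),
              noiseSigma = unlist(x$noiseSigma), seed = unlist(x$seed))
}

#' Write the tiny noiseless phantom dataset used for smoke training
#'
#' Two (by default) noiseless 8^3 phantoms with mild jitter, the fixture
#' that [smokeConfig()] training is expected to overfit.
#'
#' @param dir output directory.
#' @param nCases number of cases.
#' @param seed integer seed.
#' @return character vector of case ids, invisibly.
#' @export
smokePhantomDataset <- function(dir, nCases = 2L, seed = 11L) {
  generateDataset(nCases, dir,
                  PhantomSpec(shape = c(8L, 8L, 8L), noiseSigma = 0),
                  seed = seed,
                  jitter = list(center = 0.5, radiiFrac = 0.08,
                                contrastFrac = 0.05))
}

#' Regenerate phantoms from a dataset manifest
#'
#' @param manifestPath path to the `manifest.json` written by
#'   [generateDataset()].
#' @return named list of `list(image, labels)` cases.
#' @export
regenerateFromManifest <- function(manifestPath) {
  manifest <- jsonlite::read_json(manifestPath)
  lapply(manifest, function(x) generatePhantom(specFromList(x)))
}
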