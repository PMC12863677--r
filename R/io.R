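## NIfTI input/output in the BraTS case-directory layout:
## <case>/<case>_{t1,t1ce,t2,flair,seg}.nii.gz

#' Write one case in BraTS layout
#'
#' @param image a [MultiModalVolume].
#' @param labels a [LabelMap] or `NULL`.
#' @param dir the case directory (created if needed).
#' @param caseId the case id used in the file names; defaults to the
#'   directory basename.
#' @return `dir`, invisibly.
#' @export
writeCase <- function(image, labels = NULL, dir, caseId = basename(dir)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- volArray(image)
  sp <- spacing(image)
  for (m in seq_along(channelNames(image))) {
    ch <- x[m, , , ]
    img <- RNifti::asNifti(ch, pixdim = sp)
    RNifti::writeNifti(img, file.path(dir, sprintf(
      "%s_%s.nii.gz", caseId, channelNames(image)[m])))
  }
  if (!is.null(labels)) {
    seg <- RNifti::asNifti(labelArray(labels), pixdim = spacing(labels))
    RNifti::writeNifti(seg, file.path(dir, sprintf("%s_seg.nii.gz", caseId)),
                       datatype = "int16")
  }
  invisible(dir)
}

#' Read one case from BraTS layout
#'
#' @param dir the case directory.
#' @param caseId the case id in the file names; defaults to the directory
#'   basename.
#' @param withLabels read the `_seg` volume too, when present.
#' @return list with `image` ([MultiModalVolume]) and `labels` ([LabelMap]
#'   or `NULL`).
#' @export
readCase <- function(dir, caseId = basename(dir), withLabels = TRUE) {
  chans <- BRATS_CHANNELS
  vols <- lapply(chans, function(m) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", caseId, m))
    if (!file.exists(f)) stop("missing modality file: ", f)
    RNifti::readNifti(f)
  })
  sp <- RNifti::pixdim(vols[[1L]])[1:3]
  d <- dim(vols[[1L]])
  x <- array(0, c(length(chans), d))
  for (m in seq_along(chans)) x[m, , , ] <- as.array(vols[[m]])
  image <- MultiModalVolume(x, sp, chans)
  labels <- NULL
  segFile <- file.path(dir, sprintf("%s_seg.nii.gz", caseId))
  if (withLabels && file.exists(segFile)) {
    seg <- RNifti::readNifti(segFile)
    labels <- LabelMap(array(as.integer(round(as.array(seg))), dim(seg)), sp)
  }
  list(image = image, labels = labels)
}

#' List the case ids of a BraTS-layout dataset directory
#'
#' @param dir dataset directory containing one sub-directory per case.
#' @return character vector of case ids.
#' @export
listCases <- function(dir) {
  ids <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  sort(ids[vapply(ids, function(id)
    file.exists(file.path(dir, id, sprintf("%s_t1.nii.gz", id))), logical(1))])
}

#' Write a predicted label map as NIfTI
#'
#' @param labels a [LabelMap].
#' @param path output `.nii.gz` path.
#' @param reference optional NIfTI path whose header/affine is reused.
#' @return `path`, invisibly.
#' @export
writeLabelNifti <- function(labels, path, reference = NULL) {
  arr <- labelArray(labels)
  img <- if (!is.null(reference))
    RNifti::asNifti(arr, reference = RNifti::readNifti(reference))
  else RNifti::asNifti(arr, pixdim = spacing(labels))
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
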