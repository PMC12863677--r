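## Evaluation metrics: voxel confusion counts, Dice similarity coefficient
## DSC = 2TP / (2TP + FP + FN), sensitivity TP / (TP + FN), specificity
## TN / (TN + FP), and the robust 95th-percentile Hausdorff surface
## distance in millimetres.

#' Voxelwise confusion counts
#'
#' @param pred,ref logical (or 0/1) arrays of identical shape.
#' @return list with integer `TP`, `FP`, `FN`, `TN`.
#' @export
confusionCounts <- function(pred, ref) {
  pred <- asBinaryMask(pred)
  ref <- asBinaryMask(ref)
  if (!identical(dim(pred), dim(ref)))
    stop("pred and ref must have identical shapes")
  TP <- sum(pred & ref)
  FP <- sum(pred & !ref)
  FN <- sum(!pred & ref)
  TN <- sum(!pred & !ref)
  list(TP = TP, FP = FP, FN = FN, TN = TN)
}

asBinaryMask <- function(x) {
  if (is.logical(x)) return(x)
  u <- unique(as.vector(x))
  if (!all(u %in% c(0, 1))) stop("mask must be binary (logical or 0/1)")
  array(x != 0, dim(x))
}

#' Dice similarity coefficient
#'
#' `DSC = 2TP / (2TP + FP + FN)`. When prediction and reference are both
#' empty (TP = FP = FN = 0) the score is defined as 1, the perfect-
#' agreement convention used in BraTS evaluation.
#'
#' @param counts confusion counts from [confusionCounts()].
#' @return numeric in \[0, 1\].
#' @export
diceScore <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) return(1)
  2 * counts$TP / den
}

#' Sensitivity (true positive rate)
#'
#' `TP / (TP + FN)`; defined as 1 when the reference contains no positive
#' voxels.
#'
#' @inheritParams diceScore
#' @return numeric in \[0, 1\].
#' @export
sensitivity <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) return(1)
  counts$TP / den
}

#' Specificity (true negative rate)
#'
#' `TN / (TN + FP)`; defined as 1 when the reference contains no negative
#' voxels.
#'
#' @inheritParams diceScore
#' @return numeric in \[0, 1\].
#' @export
specificity <- function(counts) {
  den <- counts$TN + counts$FP
  if (den == 0) return(1)
  counts$TN / den
}

## Boundary voxels: mask minus its erosion under the 6-connected (face
## neighbour) structuring element; voxels on the volume border count as
## boundary.
boundaryVoxels <- function(mask) {
  d <- dim(mask)
  interior <- mask
  shift <- function(m, axis, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    n <- d[axis]
    if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
    else        { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift(mask, axis, by)
  mask & !interior
}

## millimetre coordinates of the TRUE voxels of a mask
surfaceCoords <- function(mask, spacing) {
  b <- boundaryVoxels(mask)
  idx <- which(b, arr.ind = TRUE)
  sweep(idx, 2, spacing, `*`)
}

## for each row of A (n x 3), min Euclidean distance to the rows of B
minDistances <- function(A, B, chunk = 512L) {
  nA <- nrow(A)
  out <- numeric(nA)
  b2 <- rowSums(B * B)
  for (i in seq(1L, nA, chunk)) {
    j <- min(i + chunk - 1L, nA)
    Ai <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Ai * Ai), b2, `+`) - 2 * Ai %*% t(B)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95th-percentile Hausdorff surface distance (mm)
#'
#' The maximum over both directions of the 95th percentile (linear-
#' interpolation convention) of Euclidean distances from each boundary
#' voxel of one mask to the nearest boundary voxel of the other, where the
#' boundary is the mask minus its 6-connected erosion and distances are in
#' millimetres under `spacing`.
#'
#' @param pred,ref logical (or 0/1) arrays of identical shape.
#' @param spacing numeric voxel spacing (mm) per axis.
#' @param emptyValue value returned when either mask is empty: `NaN` by
#'   default, or e.g. 373.13 in BraTS-compatible penalty mode.
#' @return numeric distance in mm (>= 0), or `emptyValue`.
#' @export
hd95 <- function(pred, ref, spacing = c(1, 1, 1), emptyValue = NaN) {
  pred <- asBinaryMask(pred)
  ref <- asBinaryMask(ref)
  if (!identical(dim(pred), dim(ref)))
    stop("pred and ref must have identical shapes")
  if (!any(pred) || !any(ref)) return(emptyValue)
  A <- surfaceCoords(pred, spacing)
  B <- surfaceCoords(ref, spacing)
  dAB <- linQuantile(minDistances(A, B), 0.95)
  dBA <- linQuantile(minDistances(B, A), 0.95)
  max(dAB, dBA)
}

#' Evaluate a predicted label map against a reference
#'
#' Computes Dice, sensitivity, specificity and HD95 for each of the three
#' nested tumor regions.
#'
#' @param pred,ref [LabelMap]s or rank-3 integer arrays over \{0, 1, 2, 4\}.
#' @param spacing numeric voxel spacing (mm).
#' @param emptyValue passed to [hd95()].
#' @return data.frame with one row per region (ET, TC, WT) and columns
#'   `region`, `dice`, `sensitivity`, `specificity`, `hd95_mm`.
#' @export
evaluateSegmentation <- function(pred, ref, spacing = c(1, 1, 1),
                                 emptyValue = NaN) {
  pm <- regionsFromLabels(pred)
  rm_ <- regionsFromLabels(ref)
  rows <- lapply(c("ET", "TC", "WT"), function(rg) {
    p <- regionMask(pm, rg)
    r <- regionMask(rm_, rg)
    cc <- confusionCounts(p, r)
    data.frame(region = rg, dice = diceScore(cc),
               sensitivity = sensitivity(cc), specificity = specificity(cc),
               hd95_mm = hd95(p, r, spacing, emptyValue))
  })
  do.call(rbind, rows)
}
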