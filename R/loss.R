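## Soft Dice loss, computed per channel on the sigmoid output against the
## binary region maps, with a smoothing factor epsilon = 1.
##
## The implemented default is the squared-denominator soft Dice with the
## conventional factor 2 in the numerator,
##   loss = 1 - (1/N) sum_n (2 sum(S_n R_n) + eps) / (sum(S_n^2) + sum(R_n^2) + eps),
## so that perfect overlap drives the loss to 0. `factor2 = FALSE`
## drops the factor 2, reproducing the loss formula exactly as printed in
## some descriptions of this family (where perfect overlap then plateaus
## at 1/2 rather than 0).

#' Soft Dice loss
#'
#' @param S numeric rank-4 array of predicted probabilities (channel,
#'   depth, height, width), values in \[0, 1\] (post-sigmoid).
#' @param R binary array of the same shape: per-channel reference region
#'   maps.
#' @param epsilon smoothing factor (default 1).
#' @param factor2 include the conventional factor 2 in the numerator
#'   (default `TRUE`); `FALSE` gives the plain-ratio variant whose
#'   perfect-overlap plateau is 1/2 rather than 0.
#' @return scalar loss in \[0, 1\] (factor-2 form).
#' @export
diceLoss <- function(S, R, epsilon = 1, factor2 = TRUE) {
  if (!identical(dim(S), dim(R))) stop("S and R must have identical shapes")
  if (length(S) == 0L) stop("empty tensors")
  if (epsilon <= 0) stop("epsilon must be > 0")
  N <- dim(S)[1L]
  num2 <- if (factor2) 2 else 1
  terms <- vapply(seq_len(N), function(n) {
    s <- S[n, , , ]
    r <- R[n, , , ]
    (num2 * sum(s * r) + epsilon) / (sum(s * s) + sum(r * r) + epsilon)
  }, numeric(1))
  1 - mean(terms)
}

#' Gradient of the soft Dice loss with respect to the probabilities
#'
#' @inheritParams diceLoss
#' @return array like `S` holding d loss / d S.
#' @export
diceLossGrad <- function(S, R, epsilon = 1, factor2 = TRUE) {
  if (!identical(dim(S), dim(R))) stop("S and R must have identical shapes")
  N <- dim(S)[1L]
  num2 <- if (factor2) 2 else 1
  dS <- array(0, dim(S))
  for (n in seq_len(N)) {
    s <- S[n, , , ]
    r <- R[n, , , ]
    num <- num2 * sum(s * r) + epsilon
    den <- sum(s * s) + sum(r * r) + epsilon
    ## d/ds of -(1/N) * num/den
    dS[n, , , ] <- -(num2 * r * den - num * 2 * s) / (N * den * den)
  }
  dS
}

#' Stack the nested-region reference channels for the loss
#'
#' Converts a label map into the 3-channel binary target (ET, TC, WT) the
#' network is optimized against: the loss acts directly on the clinically
#' evaluated nested regions rather than on the raw label classes.
#'
#' @param labels rank-3 integer array or [LabelMap].
#' @return numeric rank-4 array (3, depth, height, width) of 0/1 values.
#' @export
regionTargets <- function(labels) {
  m <- regionsFromLabels(labels)
  d <- dim(m@et)
  out <- array(0, c(3L, d))
  out[1L, , , ] <- m@et
  out[2L, , , ] <- m@tc
  out[3L, , , ] <- m@wt
  out
}
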