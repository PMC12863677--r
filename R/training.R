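## Training harness: cross-validation folds, the Adam recipe (constant
## learning rate, batch size 1), per-epoch checkpointing for snapshot
## ensembling, and lowest-validation-loss model selection.

#' Deterministic k-fold split
#'
#' Shuffles the case ids with the given seed and partitions them into `k`
#' folds whose sizes differ by at most 1; every id appears in exactly one
#' validation fold.
#'
#' @param caseIds character vector of case ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` lists with `train` and `val` id vectors.
#' @export
makeFolds <- function(caseIds, k = 5L, seed = 1L) {
  if (k > length(caseIds))
    stop(sprintf("k = %d exceeds the number of cases (%d)", k,
                 length(caseIds)))
  shuffled <- withSeed(seed, sample(caseIds))
  assignment <- rep_len(seq_len(k), length(shuffled))
  lapply(seq_len(k), function(f)
    list(train = shuffled[assignment != f], val = shuffled[assignment == f]))
}

## ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapLeaves(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- mapLeaves(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- mapLeaves(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- mapLeaves(params, upd, `-`)
  list(params = params, state = state)
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load a network checkpoint
#'
#' Checkpoints store the parameters together with the [NetworkConfig] and
#' the [PipelineConfig] they were trained under.
#'
#' @param network a [UNet3D].
#' @param path checkpoint file path (`.rds`).
#' @param pipeline the [PipelineConfig] provenance, or `NULL`.
#' @param epoch integer epoch number, or `NA`.
#' @return `path` invisibly (`saveCheckpoint`); a list with `network`,
#'   `pipeline`, `epoch` (`loadCheckpoint`).
#' @export
saveCheckpoint <- function(network, path, pipeline = NULL, epoch = NA_integer_) {
  saveRDS(list(params = network@params, config = network@config,
               pipeline = pipeline, epoch = epoch), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  list(network = new("UNet3D", config = ck$config, params = ck$params),
       pipeline = ck$pipeline, epoch = ck$epoch)
}

#' Select snapshot checkpoints by epoch
#'
#' @param outputDir a training output directory containing
#'   `checkpoint_epoch_<n>.rds` files.
#' @param epochs integer vector of requested epochs (duplicates are an
#'   error).
#' @return character vector of checkpoint paths, in the requested order.
#' @export
selectSnapshots <- function(outputDir, epochs) {
  if (anyDuplicated(epochs))
    stop("duplicate snapshot epochs requested: ",
         paste(epochs[duplicated(epochs)], collapse = ", "))
  paths <- file.path(outputDir, sprintf("checkpoint_epoch_%03d.rds", epochs))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("no checkpoint for epoch(s): ",
         paste(epochs[missing], collapse = ", "))
  paths
}

## ---- training loop ---------------------------------------------------------

loadTrainingCases <- function(datasetDir, ids, normalization) {
  lapply(ids, function(id) {
    case <- readCase(file.path(datasetDir, id))
    if (is.null(case$labels)) stop("case ", id, " has no labels")
    norm <- normalizeVolume(volArray(case$image), normalization)
    cr <- cropToBrain(norm, labelArray(case$labels))
    list(id = id, image = cr$image, labels = cr$labels)
  })
}

#' Train one pipeline
#'
#' Runs the optimization recipe of `config` on a BraTS-layout dataset
#' (real or phantom): per epoch, draws `patchesPerCase` random patches
#' from each training case (after normalization and brain cropping),
#' augments them under the pipeline policy, and performs one Adam update
#' per patch on the soft Dice loss over the ET/TC/WT channels. After each
#' epoch the full training/validation volumes are scored by padded
#' full-volume inference; a checkpoint is written per epoch and the epoch
#' with the lowest validation loss is tagged as best. Fully seeded.
#'
#' @param config a [PipelineConfig] (see [smokeConfig()] for a fast one).
#' @param datasetDir dataset directory with one sub-directory per case.
#' @param outputDir directory for checkpoints and the training log.
#' @param trainIds,valIds case id vectors; by default all cases are used
#'   for both (overfitting/smoke mode). Use [makeFolds()] for
#'   cross-validation splits.
#' @param verbose print one line per epoch.
#' @return list with `network` (final), `log` (per-epoch data.frame),
#'   `bestEpoch`, and `outputDir`.
#' @export
trainPipeline <- function(config, datasetDir, outputDir,
                          trainIds = NULL, valIds = NULL, verbose = FALSE) {
  validObject(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  allIds <- listCases(datasetDir)
  if (length(allIds) == 0L) stop("no cases found in ", datasetDir)
  if (is.null(trainIds)) trainIds <- allIds
  if (is.null(valIds)) valIds <- trainIds
  cases <- loadTrainingCases(datasetDir, unique(c(trainIds, valIds)),
                             config@normalization)
  names(cases) <- vapply(cases, `[[`, character(1), "id")
  net <- buildNetwork(config@network, seed = config@seed)
  adam <- adamInit(net@params)
  logRows <- vector("list", config@epochs)
  logPath <- file.path(outputDir, "training_log.jsonl")
  if (file.exists(logPath)) file.remove(logPath)
  withSeed(childSeed(config@seed, 1L), {
    for (epoch in seq_len(config@epochs)) {
      losses <- numeric(0)
      for (id in trainIds) {
        case <- cases[[id]]
        for (p in seq_len(config@patchesPerCase)) {
          patch <- randomCrop(case$image, case$labels,
                              config@patchSize)
          aug <- applyAugmentations(patch$image, patch$labels,
                                    config@augmentation)
          R <- regionTargets(aug$labels)
          fw <- netForward(net, aug$image, train = TRUE)
          loss <- diceLoss(fw$y, R)
          if (!is.finite(loss))
            stop(sprintf(
              "non-finite training loss at epoch %d, case %s: %.4g",
              epoch, id, loss))
          losses <- c(losses, loss)
          dS <- diceLossGrad(fw$y, R)
          grads <- netBackward(net, fw$cache, dS)
          st <- adamStep(net@params, grads, adam, config@learningRate)
          net@params <- st$params
          adam <- st$state
        }
      }
      val <- evaluateOnCases(net, cases[valIds], config)
      row <- data.frame(epoch = epoch, train_loss = mean(losses),
                        val_loss = val$loss, dice_et = val$dice["ET"],
                        dice_tc = val$dice["TC"], dice_wt = val$dice["WT"],
                        row.names = NULL)
      logRows[[epoch]] <- row
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = 6),
          "\n", sep = "", file = logPath, append = TRUE)
      saveCheckpoint(net, file.path(outputDir,
                                    sprintf("checkpoint_epoch_%03d.rds", epoch)),
                     pipeline = config, epoch = epoch)
      if (verbose)
        message(sprintf(
          "epoch %3d  train loss %.4f  val loss %.4f  WT dice %.3f",
          epoch, mean(losses), val$loss, val$dice["WT"]))
    }
  })
  log <- do.call(rbind, logRows)
  bestEpoch <- log$epoch[which.min(log$val_loss)]
  writeLines(sprintf("checkpoint_epoch_%03d.rds", bestEpoch),
             file.path(outputDir, "best_checkpoint.txt"))
  utils::write.csv(log, file.path(outputDir, "training_log.csv"),
                   row.names = FALSE)
  list(network = net, log = log, bestEpoch = bestEpoch, outputDir = outputDir)
}

## Full-volume scoring of already normalized+cropped cases: pad to the
## network multiple, forward, unpad, then loss and per-region Dice.
evaluateOnCases <- function(net, cases, config) {
  mult <- as.integer(2^config@network@levels)
  losses <- numeric(length(cases))
  dice <- matrix(0, length(cases), 3,
                 dimnames = list(NULL, c("ET", "TC", "WT")))
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    pd <- padToMultiple(case$image, mult)
    fw <- netForward(net, pd$image, train = FALSE)
    probs <- unpad(fw$y, pd$pad)
    R <- regionTargets(case$labels)
    losses[i] <- diceLoss(probs, R)
    masks <- binarize(probs)
    ref <- regionsFromLabels(case$labels)
    for (rg in c("ET", "TC", "WT"))
      dice[i, rg] <- diceScore(confusionCounts(regionMask(masks, rg),
                                               regionMask(ref, rg)))
  }
  list(loss = mean(losses), dice = colMeans(dice))
}
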