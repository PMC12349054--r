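# End-to-end pipeline commands. These are the programmatic backends of the
# command-line interface in inst/cli/wdvessel.R (verbs: synth, train, eval,
# predict, ablate); every command is an ordinary exported function so the
# whole pipeline is scriptable from R.

#' Generate a phantom dataset (pipeline command)
#'
#' @param outDir output directory.
#' @param n number of phantoms.
#' @param size phantom edge length (pixels).
#' @param seed base seed.
#' @param ... further [phantomConfig()] parameters.
#' @return the manifest, invisibly.
#' @export
cmdSynth <- function(outDir, n = 8L, size = 64L, seed = 1L, ...) {
  generateDataset(n, phantomConfig(size = size, seed = seed, ...), outDir)
}

#' Train on a phantom dataset (pipeline command)
#'
#' Loads the dataset manifest, preprocesses every record (standardize +
#' CLAHE), trains with Adam under the composite BCE + Dice loss (optional
#' eightfold augmentation, 20% validation split for best-Dice checkpoint
#' selection) and saves the checkpoint.
#'
#' @param dataDir dataset directory from [cmdSynth()].
#' @param checkpointPath where to save the trained checkpoint.
#' @param epochs,batchSize,lr,decayEvery,augment,valFraction,maxSteps,seed
#'   training settings, see [trainModel()].
#' @param baseChannels,patchSize,useWce,useDce,useGft,useDsc,skipMode,useBn
#'   model settings, see [vesselNet()].
#' @param logFile optional JSON-lines training log.
#' @param verbose print progress.
#' @return the [trainModel()] result, invisibly.
#' @export
cmdTrain <- function(dataDir, checkpointPath, epochs = 20L, batchSize = 4L,
                     lr = 1e-3, decayEvery = 50L, augment = TRUE,
                     valFraction = 0.2, maxSteps = Inf, seed = 1L,
                     baseChannels = 16L, patchSize = 2L, useWce = TRUE,
                     useDce = TRUE, useGft = TRUE, useDsc = TRUE,
                     skipMode = "add", useBn = TRUE, logFile = NULL,
                     verbose = FALSE) {
  records <- loadDataset(dataDir)
  if (length(records) == 0L) stop("dataset is empty")
  records <- lapply(records, preprocessRecord)
  d <- dim(records[[1]]$image)
  model <- vesselNet(inputSize = d, baseChannels = baseChannels,
                     patchSize = patchSize, useWce = useWce, useDce = useDce,
                     useGft = useGft, useDsc = useDsc, skipMode = skipMode,
                     useBn = useBn, seed = seed)
  fit <- trainModel(model, records, epochs = epochs, batchSize = batchSize,
                    lr = lr, decayEvery = decayEvery, augment = augment,
                    valFraction = valFraction, maxSteps = maxSteps,
                    seed = seed, logFile = logFile, verbose = verbose)
  saveCheckpoint(fit$model, checkpointPath)
  invisible(fit)
}

#' Evaluate a checkpoint on a dataset (pipeline command)
#'
#' @param checkpointPath checkpoint from [cmdTrain()].
#' @param dataDir dataset directory.
#' @param outPrefix if non-NULL, writes `<outPrefix>.csv` (per image) and
#'   `<outPrefix>.json` (aggregate).
#' @param threshold binarization threshold.
#' @return the [evaluateModel()] result, invisibly.
#' @export
cmdEval <- function(checkpointPath, dataDir, outPrefix = NULL,
                    threshold = 0.5) {
  model <- loadCheckpoint(checkpointPath)
  records <- lapply(loadDataset(dataDir), preprocessRecord)
  d <- dim(records[[1]]$image)
  if (!identical(as.integer(d), model@config$inputSize))
    stop("checkpoint expects ", paste(model@config$inputSize, collapse = "x"),
         " images but the dataset is ", paste(d, collapse = "x"))
  res <- evaluateModel(model, records, threshold)
  if (!is.null(outPrefix))
    writeMetrics(res, paste0(outPrefix, ".csv"), paste0(outPrefix, ".json"))
  invisible(res)
}

#' Segment one image (pipeline command)
#'
#' Reads an image, preprocesses it, pads reflectively to the model's input
#' size if required (with a warning), and writes the probability map and the
#' thresholded binary mask as PNGs.
#'
#' @param checkpointPath checkpoint from [cmdTrain()].
#' @param imagePath input PNG.
#' @param outProb,outBinary output PNG paths.
#' @param threshold binarization threshold.
#' @return the probability matrix, invisibly.
#' @export
cmdPredict <- function(checkpointPath, imagePath, outProb, outBinary,
                       threshold = 0.5) {
  model <- loadCheckpoint(checkpointPath)
  img <- png::readPNG(imagePath) * 255
  if (length(dim(img)) == 3L) img <- standardizeImage(img)
  rec <- preprocessRecord(list(image = img))
  x <- rec$image
  target <- model@config$inputSize
  d0 <- dim(x)
  if (!identical(as.integer(d0), target)) {
    if (any(d0 > target))
      stop("image larger than the model input ",
           paste(target, collapse = "x"))
    warning("padding image reflectively from ", paste(d0, collapse = "x"),
            " to ", paste(target, collapse = "x"))
    x <- padReflect(x, target[1], target[2])
  }
  pr <- predictProb(model, x)[seq_len(d0[1]), seq_len(d0[2]), drop = FALSE]
  png::writePNG(pr, outProb)
  png::writePNG(matrix(as.numeric(pr >= threshold), d0[1], d0[2]), outBinary)
  invisible(pr)
}

padReflect <- function(x, H, W) {
  while (nrow(x) < H)
    x <- rbind(x, x[nrow(x):max(1L, 2L * nrow(x) - H + 1L), , drop = FALSE])
  while (ncol(x) < W)
    x <- cbind(x, x[, ncol(x):max(1L, 2L * ncol(x) - W + 1L), drop = FALSE])
  x[seq_len(H), seq_len(W), drop = FALSE]
}

#' Run the component ablation matrix (pipeline command)
#'
#' Trains and evaluates the full model and the four single-component
#' ablations (wavelet encoder, deformable encoder, gated fusion, separable
#' decoder each replaced by its standard twin) under identical settings.
#'
#' @param dataDir dataset directory.
#' @param epochs,seed,baseChannels training/model settings.
#' @param verbose print progress.
#' @return data.frame with one row per variant: parameters and aggregate
#'   metrics.
#' @export
cmdAblate <- function(dataDir, epochs = 5L, seed = 1L, baseChannels = 16L,
                      verbose = FALSE) {
  records <- lapply(loadDataset(dataDir), preprocessRecord)
  d <- dim(records[[1]]$image)
  variants <- list(
    full = list(),
    no_wce = list(useWce = FALSE), no_dce = list(useDce = FALSE),
    no_gft = list(useGft = FALSE), no_dsc = list(useDsc = FALSE))
  rows <- lapply(names(variants), function(nm) {
    args <- c(list(inputSize = d, baseChannels = baseChannels, seed = seed),
              variants[[nm]])
    model <- do.call(vesselNet, args)
    fit <- trainModel(model, records, epochs = epochs, augment = FALSE,
                      valFraction = 0, seed = seed, verbose = verbose)
    res <- evaluateModel(fit$model, records)
    data.frame(variant = nm, parameters = countParams(fit$model)$total,
               Acc = res$summary$mean$Acc, Se = res$summary$mean$Se,
               Sp = res$summary$mean$Sp, F1 = res$summary$mean$F1,
               AUC = res$summary$mean$AUC)
  })
  do.call(rbind, rows)
}
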