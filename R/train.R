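# Training: Adam with the step-decay schedule (initial learning rate 1e-3,
# multiplied by 0.1 every 50 epochs), composite BCE + Dice loss, gradient
# accumulation over a mini-batch, optional eightfold dihedral augmentation,
# optional validation split with best-by-Dice checkpoint selection.

newAdam <- function(ps, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- new.env(parent = emptyenv())
  st$v <- new.env(parent = emptyenv())
  for (nm in ps$order) {
    st$m[[nm]] <- ps$params[[nm]] * 0
    st$v[[nm]] <- ps$params[[nm]] * 0
  }
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adamStep <- function(ps, st, grads, lr) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    ps$params[[nm]] <- ps$params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + st$eps)
  }
  invisible(NULL)
}

# one optimizer update on a batch of (image, mask) pairs; returns mean loss
trainStep <- function(model, batch, st, lr, clipNorm = 1) {
  tape <- adTape()
  total <- NULL
  ctxs <- list()
  for (b in batch) {
    out <- netForward(model, b$image, tape = tape, training = TRUE)
    ctxs[[length(ctxs) + 1L]] <- out$ctx
    mask <- b$mask
    if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
    ls <- opCompositeLoss(tape, out$logits, out$prob, mask)
    total <- if (is.null(total)) ls else opAdd(tape, total, ls)
  }
  total <- opScale(tape, total, 1 / length(batch))
  adBackward(tape, total)
  grads <- list()
  for (ctx in ctxs) {
    for (nm in ls(ctx$leaves)) {
      g <- ctx$leaves[[nm]]$grad
      if (is.null(g)) next
      grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
    }
  }
  # global-norm gradient clipping guards the early epochs against blow-ups
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(gn) && gn > clipNorm)
    grads <- lapply(grads, function(g) g * clipNorm / gn)
  adamStep(model@ps, st, grads, lr)
  vof(total)
}

scheduledLr <- function(lr0, epoch, decayEvery = 50L, factor = 0.1) {
  lr0 * factor^((epoch - 1L) %/% decayEvery)
}

#' Train the segmentation network
#'
#' Full-image training with Adam and the composite BCE + Dice loss. One step
#' is one optimizer update on a mini-batch; gradients are averaged over the
#' batch. The learning rate starts at `lr` and is multiplied by 0.1 every
#' `decayEvery` epochs. When a validation set is supplied, the returned model
#' is the checkpoint with the best validation Dice; otherwise the final
#' state. Fully seeded: equal seeds reproduce the run.
#'
#' @param model a [VesselNet-class] object (modified in place and returned).
#' @param records list of records, each a list with `image` (`H x W` matrix
#'   in `[0, 255]`) and `mask` (binary `H x W` matrix).
#' @param epochs number of passes over the (possibly augmented) records.
#' @param batchSize mini-batch size (default 4).
#' @param lr initial Adam learning rate.
#' @param decayEvery epochs between learning-rate decays by 0.1.
#' @param augment apply eightfold dihedral augmentation to the records before
#'   training.
#' @param valFraction fraction of records held out for validation-based
#'   checkpoint selection (0 disables; selection then falls back to the
#'   final state).
#' @param maxSteps optional cap on the total number of optimizer updates.
#' @param clipNorm global gradient-norm clipping threshold (stabilizes the
#'   early epochs; set `Inf` to disable).
#' @param seed RNG seed for shuffling and the validation split.
#' @param logFile optional path; one JSON object per epoch with epoch, lr,
#'   mean training loss and validation Dice is appended.
#' @param verbose print per-epoch progress.
#' @return list with `model`, `history` (data.frame of epoch, lr, loss,
#'   val_dice) and `steps` (optimizer updates performed).
#' @export
trainModel <- function(model, records, epochs = 10L, batchSize = 4L,
                       lr = 1e-3, decayEvery = 50L, augment = FALSE,
                       valFraction = 0, maxSteps = Inf, seed = 1L,
                       clipNorm = 1, logFile = NULL, verbose = FALSE) {
  if (length(records) == 0L) stop("no training records supplied")
  withSeed(seed, {
    val <- list()
    if (valFraction > 0 && length(records) >= 2L) {
      nval <- max(1L, floor(valFraction * length(records)))
      vi <- sample(length(records), nval)
      val <- records[vi]
      records <- records[-vi]
    }
    if (augment)
      records <- do.call(c, lapply(records, augment8))
    st <- newAdam(model@ps, lr = lr)
    steps <- 0L
    bestDice <- -Inf
    bestCkpt <- NULL
    hist <- data.frame()
    for (ep in seq_len(epochs)) {
      if (steps >= maxSteps) break
      lrEp <- scheduledLr(lr, ep, decayEvery)
      ord <- sample(length(records))
      losses <- c()
      for (i0 in seq(1L, length(ord), by = batchSize)) {
        if (steps >= maxSteps) break
        idx <- ord[i0:min(i0 + batchSize - 1L, length(ord))]
        losses <- c(losses, trainStep(model, records[idx], st, lrEp, clipNorm))
        steps <- steps + 1L
      }
      vd <- NA_real_
      if (length(val) > 0L) {
        vd <- mean(vapply(val, function(r) {
          pr <- predictProb(model, r$image)
          sc <- segScores(confusionCounts(pr >= 0.5, r$mask))
          sc$dice
        }, numeric(1)))
        if (!is.na(vd) && vd > bestDice) {
          bestDice <- vd
          bestCkpt <- tempfile(fileext = ".ckpt")
          saveCheckpoint(model, bestCkpt)
        }
      }
      row <- data.frame(epoch = ep, lr = lrEp, loss = mean(losses),
                        val_dice = vd)
      hist <- rbind(hist, row)
      if (!is.null(logFile))
        cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = NA),
            "\n", sep = "", file = logFile, append = TRUE)
      if (verbose)
        message(sprintf("epoch %d  lr %.2g  loss %.4f  val dice %s",
                        ep, lrEp, mean(losses),
                        if (is.na(vd)) "-" else sprintf("%.3f", vd)))
    }
    if (!is.null(bestCkpt)) model <- loadCheckpoint(bestCkpt)
    list(model = model, history = hist, steps = steps)
  })
}
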