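#' @import methods
NULL

#' VesselNet: dual-domain vessel segmentation network
#'
#' S4 container for the assembled segmentation network: configuration, the
#' parameter store (an environment holding all named weight arrays and batch
#' normalization running statistics), and an optimizer-state slot used during
#' training.
#'
#' The architecture is a U-shaped dual encoder: a wavelet convolution encoder
#' (Haar subband decomposition with learned processing of the approximation
#' band) and a deformable convolution encoder (learned sampling offsets) run
#' in parallel over three stages; their stage outputs are fused by shared 1x1
#' convolutions; the deepest fused map is max-pooled to 1/8 resolution and
#' refined by a gated cross-attention bottleneck; a depthwise-separable
#' decoder with additive skips restores full resolution and emits a
#' per-pixel vessel probability.
#'
#' @slot config list of architecture settings (see [vesselNet()]).
#' @slot ps environment: the parameter store.
#' @export
setClass("VesselNet", representation(config = "list", ps = "environment"))

setValidity("VesselNet", function(object) {
  cfg <- object@config
  hw <- cfg$inputSize
  if (any(hw %% 8L != 0L))
    return("inputSize must be divisible by 8")
  if (any((hw %/% 8L) %% cfg$patchSize != 0L))
    return("patchSize must divide inputSize / 8 (the bottleneck grid)")
  if (cfg$baseChannels < 1L) return("baseChannels must be >= 1")
  if (!cfg$skipMode %in% c("add", "concat"))
    return("skipMode must be 'add' or 'concat'")
  TRUE
})

setMethod("show", "VesselNet", function(object) {
  cfg <- object@config
  cat("VesselNet dual-domain segmentation network\n")
  cat(sprintf("  input: %d x %d grayscale, base channels C' = %d, patch size %d\n",
              cfg$inputSize[1], cfg$inputSize[2], cfg$baseChannels,
              cfg$patchSize))
  onoff <- function(x) if (x) "on" else "off (standard-conv twin)"
  cat(sprintf("  wavelet encoder: %s | deformable encoder: %s\n",
              onoff(cfg$useWce), onoff(cfg$useDce)))
  cat(sprintf("  gated fusion bottleneck: %s | separable decoder: %s\n",
              onoff(cfg$useGft), onoff(cfg$useDsc)))
  cat(sprintf("  skip mode: %s | batch norm: %s\n", cfg$skipMode,
              if (cfg$useBn) "on" else "off"))
  cat(sprintf("  trainable parameters: %s\n",
              format(countParams(object)$total, big.mark = ",")))
})

#' Build the segmentation network
#'
#' Constructs and deterministically initializes the full dual-encoder
#' network. Equal seeds give bit-identical parameter vectors. The four
#' component switches implement ablations: a disabled component is replaced
#' by a standard-convolution twin with the same interface, never removed, so
#' every variant builds and runs end to end.
#'
#' @param inputSize integer length-2 (H, W), both divisible by 8, and `H/8`
#'   divisible by `patchSize` (the gated-fusion bottleneck operates on a
#'   patch grid at 1/8 resolution). Scalars are taken as square.
#' @param baseChannels C', the stage-1 channel width; stages use C', 2C', 4C'.
#' @param patchSize patch edge (pixels) for bottleneck tokenization.
#' @param useWce,useDce,useGft,useDsc component switches (all `TRUE` for the
#'   full model).
#' @param skipMode `"add"` (1x1-projected additive skips) or `"concat"`
#'   (concatenation followed by 1x1 projection).
#' @param useBn enable batch normalization in the encoder blocks (disable for
#'   strictly deterministic, statistics-free forward passes in analyses).
#' @param inChannels input image channels (1 for the standard grayscale
#'   pipeline).
#' @param seed integer seed for weight initialization.
#' @return a [VesselNet-class] object.
#' @examples
#' net <- vesselNet(inputSize = 32, baseChannels = 4, seed = 1)
#' net
#' @export
vesselNet <- function(inputSize = 64L, baseChannels = 32L, patchSize = 2L,
                      useWce = TRUE, useDce = TRUE, useGft = TRUE,
                      useDsc = TRUE, skipMode = "add", useBn = TRUE,
                      inChannels = 1L, seed = 1L) {
  if (length(inputSize) == 1L) inputSize <- c(inputSize, inputSize)
  cfg <- list(inputSize = as.integer(inputSize),
              baseChannels = as.integer(baseChannels),
              patchSize = as.integer(patchSize),
              useWce = isTRUE(useWce), useDce = isTRUE(useDce),
              useGft = isTRUE(useGft), useDsc = isTRUE(useDsc),
              skipMode = skipMode, useBn = isTRUE(useBn),
              inChannels = as.integer(inChannels), seed = as.integer(seed))
  ps <- newParamStore()
  withSeed(cfg$seed, {
    initWceEncoder(ps, cfg)
    initDceEncoder(ps, cfg)
    cp <- cfg$baseChannels
    initConv(ps, "fuse1", 1L, 2L * cp, 2L * cp)
    initConv(ps, "fuse2", 1L, 4L * cp, 4L * cp)
    initConv(ps, "fuse3", 1L, 8L * cp, 8L * cp)
    if (cfg$useGft) initGft(ps, cfg) else initGftTwin(ps, cfg)
    initDecoder(ps, cfg)
  })
  methods::new("VesselNet", config = cfg, ps = ps)
}

# Full forward pass on one image. `x` is an H x W matrix in [0, 255] (or an
# H x W x 1 array); intensities are mapped to [0, 1] before the network.
# Returns the probability node (tape != NULL) or a plain H x W x 1 array.
netForward <- function(model, x, tape = NULL, training = FALSE) {
  cfg <- model@config
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != cfg$inputSize[1] || d[2] != cfg$inputSize[2])
    stop("input is ", d[1], " x ", d[2], " but the model was built for ",
         cfg$inputSize[1], " x ", cfg$inputSize[2])
  ctx <- makeCtx(model@ps, tape, training, cfg)
  x <- x / 255
  w <- wceEncoderForward(ctx, x)
  dc <- dceEncoderForward(ctx, x)
  f1 <- opRelu(tape, applyConv(ctx, "fuse1", opConcatC(tape, w[[1]], dc[[1]]), 1L))
  f2 <- opRelu(tape, applyConv(ctx, "fuse2", opConcatC(tape, w[[2]], dc[[2]]), 1L))
  f3 <- opRelu(tape, applyConv(ctx, "fuse3", opConcatC(tape, w[[3]], dc[[3]]), 1L))
  pWD <- opMaxpool2(tape, f3)
  if (cfg$useGft) {
    # second concatenation ordering, sharing the fuse3 projection weights
    fDW <- opRelu(tape, applyConv(ctx, "fuse3",
                                  opConcatC(tape, dc[[3]], w[[3]]), 1L))
    f4 <- gftForward(ctx, pWD, opMaxpool2(tape, fDW))
  } else {
    f4 <- gftTwinForward(ctx, pWD, NULL)
  }
  logits <- decoderForward(ctx, f4, list(f1, f2, f3))
  list(logits = logits, prob = opSigmoid(tape, logits), ctx = ctx)
}

#' Predict a vessel probability map
#'
#' Runs the network forward in evaluation mode (batch normalization uses its
#' running averages) and returns the per-pixel vessel probability.
#'
#' @param model a [VesselNet-class] object.
#' @param image `H x W` numeric matrix in `[0, 255]` matching the model's
#'   `inputSize`.
#' @return `H x W` matrix of probabilities in (0, 1).
#' @export
predictProb <- function(model, image) {
  out <- netForward(model, image, tape = NULL, training = FALSE)
  matrix(out$prob, nrow(image), ncol(image))
}

#' Count trainable parameters
#'
#' Exact integer parameter counts obtained by enumerating the shapes of every
#' instantiated weight array, reported per component and in total, together
#' with the dense-decoder comparison: the parameter count the decoder would
#' have if every depthwise separable convolution were replaced by its dense
#' `K x K` twin.
#'
#' @param model a [VesselNet-class] object.
#' @return list with `per_module` (named integer vector over components),
#'   `total`, `decoder_separable`, `decoder_dense` and
#'   `decoder_percent_reduction`.
#' @export
countParams <- function(model) {
  ps <- model@ps
  sizes <- vapply(ps$order, function(nm) length(ps$params[[nm]]), numeric(1))
  comp <- sub("[0-9]*\\..*$", "", ps$order)
  per <- tapply(sizes, comp, sum)
  dec <- startsWith(ps$order, "dec")
  sepCount <- 0; denseCount <- 0
  for (nm in ps$order[dec]) {
    n <- length(ps$params[[nm]])
    sepCount <- sepCount + n
    if (grepl("\\.dsc\\.dw$", nm)) {
      d <- dim(ps$params[[nm]])           # (K*K) x Cin
      cin <- d[2]
      # dense twin: K x K x Cin x Cout replaces depthwise + pointwise
      denseCount <- denseCount + d[1] * cin * cin
    } else if (grepl("\\.dsc\\.pw\\.w$", nm) || grepl("\\.dsc\\.dwb$", nm)) {
      # pointwise weights are absorbed into the dense kernel; the dense twin
      # has a single bias vector (counted via .pw.b), not a depthwise one
    } else {
      denseCount <- denseCount + n
    }
  }
  list(per_module = per, total = sum(sizes),
       decoder_separable = sepCount, decoder_dense = denseCount,
       decoder_percent_reduction =
         paramReductionPercent(sepCount, denseCount))
}

#' Composite segmentation loss: binary cross-entropy plus Dice
#'
#' `loss = BCE(pred, mask) + (1 - softDice(pred, mask))` with equal weights.
#' The soft Dice term uses a smoothing constant of 1 in numerator and
#' denominator, so the loss is exactly zero when `pred == mask`. Predictions
#' are clamped away from 0/1 by `1e-7` inside the logarithms.
#'
#' @param pred numeric array of probabilities in (0, 1).
#' @param mask binary array of the same shape.
#' @return non-negative scalar loss.
#' @export
compositeLoss <- function(pred, mask) {
  if (!identical(dim(pred) %||% length(pred), dim(mask) %||% length(mask)))
    stop("pred and mask must have the same shape")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  bce <- -mean(mask * log(p) + (1 - mask) * log(1 - p))
  dice <- (2 * sum(pred * mask) + 1) / (sum(pred) + sum(mask) + 1)
  bce + (1 - dice)
}

# mean binary cross-entropy computed from logits (the numerically stable
# form: softplus(z) - m*z, with pullback sigmoid(z) - m, which never
# vanishes under saturation)
opBCELogits <- function(tape, z, mask) {
  zv <- vof(z)
  n <- length(zv)
  y <- sum(pmax(zv, 0) - zv * mask + log1p(exp(-abs(zv)))) / n
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    accumGrad(z, g * (1 / (1 + exp(-zv)) - mask) / n)
  })
}

# differentiable composite loss from logits and their sigmoid
opCompositeLoss <- function(tape, logits, pred, mask) {
  bce <- opBCELogits(tape, logits, mask)
  num <- opAddConst(tape, opScale(tape, opSum(tape, opMul(tape, pred, mask)), 2), 1)
  den <- opAddConst(tape, opAdd(tape, opSum(tape, pred), sum(mask)), 1)
  dice <- opDiv(tape, num, den)
  opAdd(tape, bce, opSub(tape, 1, dice))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive containing the configuration echo,
#' every named parameter array and the batch normalization running
#' statistics; loading reconstructs an identical model.
#'
#' @param model a [VesselNet-class] object.
#' @param path file path for the checkpoint.
#' @export
saveCheckpoint <- function(model, path) {
  ps <- model@ps
  obj <- list(config = model@config,
              params = mget(ps$order, envir = ps$params),
              state = as.list(ps$state),
              order = ps$order)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  model <- do.call(vesselNet, obj$config[c("inputSize", "baseChannels",
                                           "patchSize", "useWce", "useDce",
                                           "useGft", "useDsc", "skipMode",
                                           "useBn", "inChannels", "seed")])
  ps <- model@ps
  for (nm in obj$order) ps$params[[nm]] <- obj$params[[nm]]
  for (nm in names(obj$state)) ps$state[[nm]] <- obj$state[[nm]]
  model
}

#' Read a model configuration file
#'
#' Reads a YAML file whose keys match the [vesselNet()] arguments
#' (`inputSize`, `baseChannels`, `patchSize`, `useWce`, `useDce`, `useGft`,
#' `useDsc`, `skipMode`, `useBn`, `inChannels`, `seed`) and returns the
#' argument list; unknown keys are an error naming the offending field.
#'
#' @param path YAML file path.
#' @return named list suitable for `do.call(vesselNet, ...)`.
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(vesselNet))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg
}
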