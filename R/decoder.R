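#' Depthwise separable convolution
#'
#' Factorizes a dense `K x K` convolution into (1) a depthwise stage that
#' filters each input channel independently with its own `K x K` kernel, and
#' (2) a pointwise `1 x 1` stage that mixes channels linearly, reducing the
#' parameter count from \eqn{K^2 C_{in} C_{out}} to
#' \eqn{K^2 C_{in} + C_{in} C_{out}} (see [paramAccounting()]).
#'
#' @param x input map, `H x W x Cin` array (or `H x W` matrix).
#' @param depthwise `K x K x Cin` array of per-channel spatial kernels.
#' @param pointwise `Cout x Cin` matrix of channel-mixing weights.
#' @param biasDepthwise,biasPointwise optional bias vectors (lengths `Cin`
#'   and `Cout`).
#' @return `H x W x Cout` array; spatial dimensions are preserved (zero
#'   padding, stride 1).
#' @export
depthwiseSeparableConv <- function(x, depthwise, pointwise,
                                   biasDepthwise = NULL,
                                   biasPointwise = NULL) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  dd <- dim(depthwise)
  if (length(dd) != 3L || dd[1] != dd[2])
    stop("depthwise must be a K x K x Cin array")
  K <- dd[1]; cin <- dd[3]
  if (dim(x)[3] != cin) stop("depthwise kernel count does not match channels")
  if (ncol(pointwise) != cin)
    stop("pointwise must be a Cout x Cin matrix")
  if (is.null(biasDepthwise)) biasDepthwise <- numeric(cin)
  if (is.null(biasPointwise)) biasPointwise <- numeric(nrow(pointwise))
  y <- cpp_depthwise_fwd(x, matrix(depthwise, K * K, cin), biasDepthwise,
                         K, (K - 1L) %/% 2L)
  cpp_conv2d_fwd(y, t(pointwise), biasPointwise, 1L, 0L)
}

#' Parameter accounting for depthwise separable convolution
#'
#' Closed-form parameter counts (weights only, no biases) for a dense
#' `K x K` convolution versus its depthwise separable factorization, and the
#' resulting reduction factor
#' \deqn{\frac{K^2 C_{in} + C_{in} C_{out}}{K^2 C_{in} C_{out}}
#'       = \frac{1}{K^2} + \frac{1}{C_{out}}.}
#'
#' @param K kernel size; `Cin`, `Cout` channel counts. All positive integers.
#' @return a list with integer `standard` and `separable` counts, the real
#'   `reduction_factor` (separable / standard) and `percent_reduction`
#'   (`100 * (1 - reduction_factor)`).
#' @examples
#' paramAccounting(3, 64, 256)$percent_reduction  # over 88% for deep layers
#' @export
paramAccounting <- function(K, Cin, Cout) {
  if (any(c(K, Cin, Cout) < 1) || any(c(K, Cin, Cout) %% 1 != 0))
    stop("K, Cin, Cout must be positive integers")
  standard <- K^2 * Cin * Cout
  separable <- K^2 * Cin + Cin * Cout
  factor <- 1 / K^2 + 1 / Cout
  list(standard = standard, separable = separable,
       reduction_factor = factor,
       percent_reduction = 100 * (1 - factor))
}

#' Percent reduction and percent increase between two parameter counts
#'
#' Convenience helpers for comparing model sizes: `paramReductionPercent`
#' reports how much smaller `reduced` is than `full`
#' (`100 * (1 - reduced/full)`); `paramIncreasePercent` reports how much
#' larger `larger` is than `smaller` (`100 * (larger/smaller - 1)`).
#'
#' @param reduced,full,larger,smaller positive parameter counts (any common
#'   unit, e.g. millions).
#' @return a percentage.
#' @export
paramReductionPercent <- function(reduced, full) 100 * (1 - reduced / full)

#' @rdname paramReductionPercent
#' @export
paramIncreasePercent <- function(larger, smaller) 100 * (larger / smaller - 1)

# --- decoder ----------------------------------------------------------------
# Three true upsampling stages (bilinear x2 + 1x1 channel adjustment, then a
# depthwise separable convolution, then the additive skip) followed by a
# final refinement stage at full resolution with a 1x1 projection to one
# channel and a sigmoid. Skips can alternatively be concatenated and
# projected back (skipMode = "concat"). When the separable decoder is
# ablated, each DSC is replaced by a dense 3x3 convolution twin.

initDecStage <- function(ps, name, cin, cout, cfg) {
  initConv(ps, paste0(name, ".up"), 1L, cin, cout)
  if (cfg$useDsc) initDSC(ps, paste0(name, ".dsc"), 3L, cout, cout)
  else initConv(ps, paste0(name, ".dense"), 3L, cout, cout)
  if (identical(cfg$skipMode, "concat"))
    initConv(ps, paste0(name, ".cat"), 1L, 2L * cout, cout)
}

applyDecConv <- function(ctx, name, x) {
  if (ctx$cfg$useDsc) applyDSC(ctx, paste0(name, ".dsc"), x)
  else applyConv(ctx, paste0(name, ".dense"), x, 3L)
}

decStageForward <- function(ctx, name, x, skip) {
  d <- dim(vof(x))
  up <- opResizeBilinear(ctx$tape, x, 2L * d[1], 2L * d[2])
  up <- applyConv(ctx, paste0(name, ".up"), up, 1L)
  y <- applyDecConv(ctx, name, up)
  if (identical(ctx$cfg$skipMode, "concat"))
    applyConv(ctx, paste0(name, ".cat"), opConcatC(ctx$tape, y, skip), 1L)
  else
    opAdd(ctx$tape, y, skip)
}

initDecoder <- function(ps, cfg) {
  cp <- cfg$baseChannels
  initDecStage(ps, "dec4", 8L * cp, 8L * cp, cfg)
  initDecStage(ps, "dec3", 8L * cp, 4L * cp, cfg)
  initDecStage(ps, "dec2", 4L * cp, 2L * cp, cfg)
  if (cfg$useDsc) initDSC(ps, "dec1.dsc", 3L, 2L * cp, 2L * cp)
  else initConv(ps, "dec1.dense", 3L, 2L * cp, 2L * cp)
  # zero-initialised output head: the network starts at probability 0.5
  # everywhere instead of a saturated sigmoid
  initConv(ps, "dec1.out", 1L, 2L * cp, 1L, zero = TRUE)
}

decoderForward <- function(ctx, bottleneck, skips) {
  d4 <- decStageForward(ctx, "dec4", bottleneck, skips[[3]])
  d3 <- decStageForward(ctx, "dec3", d4, skips[[2]])
  d2 <- decStageForward(ctx, "dec2", d3, skips[[1]])
  h <- applyDecConv(ctx, "dec1", d2)
  # returns logits; the sigmoid is applied by the caller (the loss is
  # computed from logits for numerical stability)
  applyConv(ctx, "dec1.out", h, 1L)
}
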