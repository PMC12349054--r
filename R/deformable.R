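#' Bilinear interpolation with a zero border
#'
#' Samples a feature map at fractional locations using standard four-neighbour
#' bilinear weighting. Locations outside `[0, H-1] x [0, W-1]` read an
#' implicit zero border, consistent with the zero padding used by the
#' convolution branches.
#'
#' @param x numeric matrix (`H x W`) or array (`H x W x C`).
#' @param points numeric vector `c(row, col)` or an `n x 2` matrix of 0-based
#'   real coordinates (row, column).
#' @return an `n x C` matrix of sampled values (a vector when `x` is a matrix
#'   and one point is given).
#' @examples
#' bilinearSample(matrix(c(0, 2, 1, 3), 2, 2), c(0.5, 0.5))  # mean of corners
#' @export
bilinearSample <- function(x, points) {
  isMat <- is.matrix(x)
  if (isMat) dim(x) <- c(dim(x), 1L)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (!all(is.finite(points))) stop("sampling locations must be finite")
  out <- cpp_bilinear_sample(x, points)
  if (isMat && nrow(points) == 1L) as.numeric(out) else out
}

#' Deformable 3x3 convolution with explicit offsets
#'
#' Evaluates \eqn{y(p) = \sum_{p_n \in R} w(p_n)\, x(p + p_n + \Delta p_n)}
#' where `R` is the kernel tap grid and the per-location, per-tap
#' displacements \eqn{\Delta p_n} are supplied as an offset field. Fractional
#' sampling positions are read by bilinear interpolation with a zero border;
#' with an all-zero offset field the operation reduces exactly to a standard
#' zero-padded convolution.
#'
#' @param x input map, `H x W x Cin` array (or `H x W` matrix).
#' @param weights kernel array `K x K x Cin x Cout` (`K` odd; tap `[kh, kw]`
#'   has displacement `(kh - (K+1)/2, kw - (K+1)/2)`).
#' @param offsets `H x W x 2K^2` array; for tap index `t = kh + K*kw`
#'   (0-based), slice `2t+1` is the row displacement and slice `2t+2` the
#'   column displacement, in pixels.
#' @param bias optional numeric vector of length `Cout`.
#' @return `H x W x Cout` array.
#' @export
deformConv <- function(x, weights, offsets, bias = NULL) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  dw <- dim(weights)
  if (length(dw) != 4L || dw[1] != dw[2] || dw[1] %% 2L == 0L)
    stop("weights must be a K x K x Cin x Cout array with K odd")
  K <- dw[1]
  if (dw[3] != dim(x)[3]) stop("kernel input channels do not match x")
  d <- dim(x)
  if (!identical(dim(offsets), c(d[1], d[2], 2L * K * K)))
    stop("offsets must be an H x W x ", 2 * K * K, " array matching x")
  if (is.null(bias)) bias <- numeric(dw[4])
  wmat <- matrix(weights, K * K * dw[3], dw[4])
  cpp_deform_fwd(x, wmat, bias, offsets, K, (K - 1L) %/% 2L)
}

# --- deformable convolution encoder -----------------------------------------
# One block: branch A = 3x3 conv + BN + ReLU; branch B = offset head (3x3
# conv, zero-initialised so training starts in the standard-convolution
# regime) followed by a deformable 3x3 conv; the branches are summed
# residually and a 1x1 conv + ReLU adjusts the channels.

initDceBlock <- function(ps, name, cin, cout) {
  initConvBNRelu(ps, paste0(name, ".a"), 3L, cin, cout)
  initConv(ps, paste0(name, ".off"), 3L, cin, 18L, zero = TRUE)
  initConv(ps, paste0(name, ".dconv"), 3L, cin, cout)
  initConv(ps, paste0(name, ".proj"), 1L, cout, cout)
}

dceBlockForward <- function(ctx, name, x) {
  ya <- applyConvBNRelu(ctx, paste0(name, ".a"), x, 3L)
  off <- applyConv(ctx, paste0(name, ".off"), x, 3L)
  yd <- opDeformConv(ctx$tape, x, getLeaf(ctx, paste0(name, ".dconv.w")),
                     getLeaf(ctx, paste0(name, ".dconv.b")), off, 3L)
  yres <- opAdd(ctx$tape, ya, yd)
  opRelu(ctx$tape, applyConv(ctx, paste0(name, ".proj"), yres, 1L))
}

# Standard-convolution twin used when the deformable encoder is ablated:
# branch B becomes a plain 3x3 convolution (no offset head).
initDceTwin <- function(ps, name, cin, cout) {
  initConvBNRelu(ps, paste0(name, ".a"), 3L, cin, cout)
  initConv(ps, paste0(name, ".dconv"), 3L, cin, cout)
  initConv(ps, paste0(name, ".proj"), 1L, cout, cout)
}

dceTwinForward <- function(ctx, name, x) {
  ya <- applyConvBNRelu(ctx, paste0(name, ".a"), x, 3L)
  yb <- applyConv(ctx, paste0(name, ".dconv"), x, 3L)
  yres <- opAdd(ctx$tape, ya, yb)
  opRelu(ctx$tape, applyConv(ctx, paste0(name, ".proj"), yres, 1L))
}

initDceEncoder <- function(ps, cfg) {
  cp <- cfg$baseChannels
  init <- if (cfg$useDce) initDceBlock else initDceTwin
  init(ps, "dce1", cfg$inChannels, cp)
  init(ps, "dce2", cp, 2L * cp)
  init(ps, "dce3", 2L * cp, 4L * cp)
}

# Three stages with 2x2 max pooling after the first two (two pooling
# operations across three layers), so stage outputs sit at H, H/2 and H/4
# with channels C', 2C', 4C'.
dceEncoderForward <- function(ctx, x) {
  fwd <- if (ctx$cfg$useDce) dceBlockForward else dceTwinForward
  s1 <- fwd(ctx, "dce1", x)
  s2 <- fwd(ctx, "dce2", opMaxpool2(ctx$tape, s1))
  s3 <- fwd(ctx, "dce3", opMaxpool2(ctx$tape, s2))
  list(s1, s2, s3)
}
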