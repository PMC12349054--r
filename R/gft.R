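# Gated fusion bottleneck: patch tokenization with learned positional
# parameters, dual-branch gated cross-attention, and a token-wise MLP head
# whose output is upsampled and added to the fused carrier.

#' Patch tokenization
#'
#' Splits an `H x W x C` feature map into `M = (H/P) * (W/P)` non-overlapping
#' `P x P` patches and flattens each to a token of dimension `D = C * P^2`.
#' The within-token order is fixed (channel slowest, then patch row, then
#' patch column) so the operation is exactly inverted by [unpatchify()].
#' An optional positional grid of shape `(H/P) x (W/P) x C` is added before
#' flattening (one learned value per patch per channel, shared by the `P^2`
#' pixels of the patch).
#'
#' @param x `H x W x C` numeric array; `P` must divide both `H` and `W`.
#' @param P patch size in pixels.
#' @param positional optional `(H/P) x (W/P) x C` array of positional
#'   parameters.
#' @return an `M x D` matrix of tokens; patches are enumerated down the rows
#'   of the patch grid first (column-major).
#' @export
patchify <- function(x, P, positional = NULL) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be an H x W x C array")
  if (d[1] %% P != 0L || d[2] %% P != 0L)
    stop("patch size ", P, " does not divide the spatial dimensions ",
         d[1], " x ", d[2])
  if (!is.null(positional)) x <- addPosCore(x, positional, P)
  patchifyCore(x, P)
}

#' Inverse of [patchify()]
#'
#' @param tokens `M x D` token matrix produced by [patchify()].
#' @param P patch size used to produce the tokens.
#' @param H,W spatial dimensions of the original map.
#' @return the reconstructed `H x W x C` array (positional parameters, if any
#'   were added, are still included; subtract them to recover the input).
#' @export
unpatchify <- function(tokens, P, H, W) {
  M <- nrow(tokens)
  if (M != (H %/% P) * (W %/% P)) stop("token count does not match H, W, P")
  unpatchifyCore(tokens, P, H, W)
}

patchifyCore <- function(x, P) {
  d <- dim(x)
  Hg <- d[1] %/% P; Wg <- d[2] %/% P
  xa <- array(x, c(P, Hg, P, Wg, d[3]))        # (r, gi, s, gj, c)
  v <- aperm(xa, c(2L, 4L, 3L, 1L, 5L))        # (gi, gj, s, r, c)
  matrix(v, Hg * Wg, P * P * d[3])
}

unpatchifyCore <- function(tokens, P, H, W) {
  Hg <- H %/% P; Wg <- W %/% P
  C <- ncol(tokens) %/% (P * P)
  v <- array(tokens, c(Hg, Wg, P, P, C))       # (gi, gj, s, r, c)
  xa <- aperm(v, c(4L, 1L, 3L, 2L, 5L))        # (r, gi, s, gj, c)
  array(xa, c(H, W, C))
}

addPosCore <- function(x, pos, P) {
  d <- dim(x)
  Hg <- d[1] %/% P; Wg <- d[2] %/% P
  if (!all(dim(pos) == c(Hg, Wg, d[3])))
    stop("positional grid must be (H/P) x (W/P) x C")
  x + pos[rep(seq_len(Hg), each = P), rep(seq_len(Wg), each = P), ,
          drop = FALSE]
}

opPatchify <- function(tape, x, P) {
  xv <- vof(x)
  d <- dim(xv)
  y <- patchifyCore(xv, P)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) accumGrad(x, unpatchifyCore(g, P, d[1], d[2])))
}

opAddPos <- function(tape, x, pos, P) {
  xv <- vof(x); pv <- vof(pos)
  y <- addPosCore(xv, pv, P)
  if (is.null(tape)) return(y)
  d <- dim(xv)
  Hg <- d[1] %/% P; Wg <- d[2] %/% P
  adNode(tape, y, function(g) {
    accumGrad(x, g)
    gp <- apply(array(g, c(P, Hg, P, Wg, d[3])), c(2L, 4L, 5L), sum)
    accumGrad(pos, gp)
  })
}

opReshapeToGrid <- function(tape, tokens, Hg, Wg) {
  tv <- vof(tokens)
  y <- array(tv, c(Hg, Wg, ncol(tv)))
  if (is.null(tape)) return(y)
  M <- nrow(tv); D <- ncol(tv)
  adNode(tape, y, function(g) accumGrad(tokens, matrix(g, M, D)))
}

#' Gated cross-attention over two token sequences
#'
#' Single-head scaled dot-product cross-attention in which each branch's keys
#' are modulated by a logistic gate driven by the other branch before a
#' residual key term is added:
#' \deqn{\tilde K_a = K_a \odot \mathrm{sigmoid}(K_b) + K_a,}
#' \deqn{Z_a = \mathrm{softmax}(Q_a \tilde K_a^\top / \sqrt{D})\, V_b,}
#' and symmetrically for the other branch. The gate selects, per feature,
#' how strongly each branch's keys are emphasised by the other branch; values
#' always cross over, so each output token is a convex mixture of the other
#' branch's value vectors.
#'
#' @param tokensA,tokensB `M x D` token matrices for the two branches.
#' @param weights a list with square `D x D` matrices `qa`, `ka`, `va`, `qb`,
#'   `kb`, `vb` (the query/key/value transforms of branches A and B).
#' @return a list with `za`, `zb` (`M x D` fused outputs) and the two
#'   attention matrices `attA`, `attB` (each row sums to one).
#' @export
gatedCrossAttention <- function(tokensA, tokensB, weights) {
  D <- ncol(tokensA)
  if (!identical(dim(tokensA), dim(tokensB)))
    stop("token sequences must have equal dimensions")
  qa <- tokensA %*% weights$qa; ka <- tokensA %*% weights$ka
  va <- tokensA %*% weights$va
  qb <- tokensB %*% weights$qb; kb <- tokensB %*% weights$kb
  vb <- tokensB %*% weights$vb
  kga <- ka * stats::plogis(kb) + ka
  kgb <- kb * stats::plogis(ka) + kb
  attA <- softmaxRows(qa %*% t(kga) / sqrt(D))
  attB <- softmaxRows(qb %*% t(kgb) / sqrt(D))
  list(za = attA %*% vb, zb = attB %*% va, attA = attA, attB = attB)
}

softmaxRows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# --- GFT layer --------------------------------------------------------------

initGft <- function(ps, cfg) {
  c2 <- 8L * cfg$baseChannels                 # fused bottleneck channels (2C)
  P <- cfg$patchSize
  gH <- cfg$inputSize[1] %/% (8L * P)
  gW <- cfg$inputSize[2] %/% (8L * P)
  D <- c2 * P * P
  addParam(ps, "gft.pos_w", array(stats::rnorm(gH * gW * c2, sd = 0.02),
                                  c(gH, gW, c2)))
  addParam(ps, "gft.pos_d", array(stats::rnorm(gH * gW * c2, sd = 0.02),
                                  c(gH, gW, c2)))
  for (nm in c("qw", "kw", "vw", "qd", "kd", "vd"))
    addParam(ps, paste0("gft.psi_", nm), xavierMat(D, D))
  initLinear(ps, "gft.mlp1", 2L * D, D)
  initLinear(ps, "gft.mlp2", D, c2, xavier = TRUE)
  initConv(ps, "gft.up", 1L, c2, c2)
}

# fWD, fDW: the two concatenation orderings of the deepest encoder features
# after the shared 1x1 fusion, max-pooled to the bottleneck resolution H/8.
# The residual carrier is fWD (the same fused map that feeds tokenization).
gftForward <- function(ctx, fWD, fDW) {
  tape <- ctx$tape
  P <- ctx$cfg$patchSize
  d <- dim(vof(fWD))
  Hg <- d[1] %/% P; Wg <- d[2] %/% P
  D <- d[3] * P * P
  aW <- opPatchify(tape, opAddPos(tape, fWD, getLeaf(ctx, "gft.pos_w"), P), P)
  aD <- opPatchify(tape, opAddPos(tape, fDW, getLeaf(ctx, "gft.pos_d"), P), P)
  qW <- opMatmul(tape, aW, getLeaf(ctx, "gft.psi_qw"))
  kW <- opMatmul(tape, aW, getLeaf(ctx, "gft.psi_kw"))
  vW <- opMatmul(tape, aW, getLeaf(ctx, "gft.psi_vw"))
  qD <- opMatmul(tape, aD, getLeaf(ctx, "gft.psi_qd"))
  kD <- opMatmul(tape, aD, getLeaf(ctx, "gft.psi_kd"))
  vD <- opMatmul(tape, aD, getLeaf(ctx, "gft.psi_vd"))
  kgW <- opAdd(tape, opMul(tape, kW, opSigmoid(tape, kD)), kW)
  kgD <- opAdd(tape, opMul(tape, kD, opSigmoid(tape, kW)), kD)
  attW <- opSoftmaxRows(tape, opScale(tape, opMatmul(tape, qW, opT(tape, kgW)),
                                      1 / sqrt(D)))
  attD <- opSoftmaxRows(tape, opScale(tape, opMatmul(tape, qD, opT(tape, kgD)),
                                      1 / sqrt(D)))
  zW <- opMatmul(tape, attW, vD)
  zD <- opMatmul(tape, attD, vW)
  h <- opRelu(tape, applyLinear(ctx, "gft.mlp1", opCbind(tape, zW, zD)))
  tok <- applyLinear(ctx, "gft.mlp2", h)
  grid <- opReshapeToGrid(tape, tok, Hg, Wg)
  up <- opResizeBilinear(tape, grid, d[1], d[2])
  opAdd(tape, applyConv(ctx, "gft.up", up, 1L), fWD)
}

opT <- function(tape, x) {
  y <- t(vof(x))
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) accumGrad(x, t(g)))
}

# Standard-convolution twin used when the gated fusion bottleneck is ablated.
initGftTwin <- function(ps, cfg) {
  c2 <- 8L * cfg$baseChannels
  initConvBNRelu(ps, "gft.twin", 3L, c2, c2)
}

gftTwinForward <- function(ctx, fWD, fDW) {
  applyConvBNRelu(ctx, "gft.twin", fWD, 3L)
}
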