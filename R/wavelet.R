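#' Single-level 2-D Haar discrete wavelet transform
#'
#' Decomposes a feature map into the four Haar subbands at half resolution.
#' For every non-overlapping 2x2 block with entries `F00` (top-left), `F01`
#' (top-right), `F10` (bottom-left) and `F11` (bottom-right), the subbands are
#' the quarter-weighted sums
#' \deqn{LL = (F00+F01+F10+F11)/4, \quad LH = (F00-F01+F10-F11)/4,}
#' \deqn{HL = (F00+F01-F10-F11)/4, \quad HH = (F00-F01-F10+F11)/4.}
#' `LL` is the approximation (local average) band; `LH`/`HL`/`HH` carry the
#' column-, row- and diagonal-difference details. With this normalization
#' `LL+LH+HL+HH` returns `F00` exactly and [haarIDWT()] is an exact inverse.
#'
#' @param x a numeric matrix (`H x W`) or array (`H x W x C`) with even
#'   spatial dimensions. Odd dimensions are an error: the transform never pads
#'   silently, so perfect reconstruction is preserved.
#' @return a list with components `ll`, `lh`, `hl`, `hh`, each of spatial size
#'   `H/2 x W/2` and the same number of channels as `x`.
#' @seealso [haarIDWT()]
#' @examples
#' s <- haarDWT(matrix(1:16, 4, 4))
#' max(abs(haarIDWT(s) - matrix(1:16, 4, 4)))
#' @export
haarDWT <- function(x) {
  isMat <- is.matrix(x)
  if (isMat) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a matrix or an H x W x C array")
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("haarDWT requires even spatial dimensions, got ",
         d[1], " x ", d[2])
  s <- dwtCore(x)
  if (isMat) s <- lapply(s, function(b) b[, , 1])
  s
}

#' Single-level 2-D Haar inverse discrete wavelet transform
#'
#' Reconstructs a full-resolution map from the four Haar subbands. Each output
#' 2x2 block is rebuilt by the sign pattern
#' \deqn{F(2i,2j) = LL+LH+HL+HH, \quad F(2i,2j+1) = LL-LH+HL-HH,}
#' \deqn{F(2i+1,2j) = LL+LH-HL-HH, \quad F(2i+1,2j+1) = LL-LH-HL+HH,}
#' the exact inverse of [haarDWT()]: `haarIDWT(haarDWT(x))` equals `x` to
#' floating-point precision.
#'
#' @param s a list with components `ll`, `lh`, `hl`, `hh` of identical shape
#'   (matrices or `H x W x C` arrays), as produced by [haarDWT()].
#' @return the reconstructed map of twice the spatial size.
#' @export
haarIDWT <- function(s) {
  bands <- s[c("ll", "lh", "hl", "hh")]
  if (any(vapply(bands, is.null, logical(1))))
    stop("s must have components ll, lh, hl, hh")
  isMat <- is.matrix(bands$ll)
  if (isMat) bands <- lapply(bands, function(b) array(b, c(dim(b), 1L)))
  dims <- vapply(bands, function(b) dim(b), integer(3))
  if (!all(dims == dims[, 1]))
    stop("all four subbands must have identical dimensions")
  y <- idwtCore(bands$ll, bands$lh, bands$hl, bands$hh)
  if (isMat) y <- y[, , 1]
  y
}

dwtCore <- function(x) {
  d <- dim(x)
  r0 <- seq(1L, d[1], 2L); r1 <- seq(2L, d[1], 2L)
  c0 <- seq(1L, d[2], 2L); c1 <- seq(2L, d[2], 2L)
  F00 <- x[r0, c0, , drop = FALSE]; F01 <- x[r0, c1, , drop = FALSE]
  F10 <- x[r1, c0, , drop = FALSE]; F11 <- x[r1, c1, , drop = FALSE]
  list(ll = (F00 + F01 + F10 + F11) / 4,
       lh = (F00 - F01 + F10 - F11) / 4,
       hl = (F00 + F01 - F10 - F11) / 4,
       hh = (F00 - F01 - F10 + F11) / 4)
}

idwtCore <- function(ll, lh, hl, hh) {
  d <- dim(ll)
  H <- 2L * d[1]; W <- 2L * d[2]
  y <- array(0, c(H, W, d[3]))
  r0 <- seq(1L, H, 2L); r1 <- seq(2L, H, 2L)
  c0 <- seq(1L, W, 2L); c1 <- seq(2L, W, 2L)
  y[r0, c0, ] <- ll + lh + hl + hh
  y[r0, c1, ] <- ll - lh + hl - hh
  y[r1, c0, ] <- ll + lh - hl - hh
  y[r1, c1, ] <- ll - lh - hl + hh
  y
}

# sign pattern of each subband over (F00, F01, F10, F11)
.dwtSigns <- list(ll = c(1, 1, 1, 1), lh = c(1, -1, 1, -1),
                  hl = c(1, 1, -1, -1), hh = c(1, -1, -1, 1))

# differentiable subband extraction (linear op; pullback scatters the
# quarter-weighted signs back onto the 2x2 blocks)
opDwtBand <- function(tape, x, band) {
  xv <- vof(x)
  y <- dwtCore(xv)[[band]]
  if (is.null(tape)) return(y)
  sg <- .dwtSigns[[band]]
  d <- dim(xv)
  adNode(tape, y, function(g) {
    gx <- array(0, d)
    r0 <- seq(1L, d[1], 2L); r1 <- seq(2L, d[1], 2L)
    c0 <- seq(1L, d[2], 2L); c1 <- seq(2L, d[2], 2L)
    gx[r0, c0, ] <- sg[1] * g / 4
    gx[r0, c1, ] <- sg[2] * g / 4
    gx[r1, c0, ] <- sg[3] * g / 4
    gx[r1, c1, ] <- sg[4] * g / 4
    accumGrad(x, gx)
  })
}

opIdwt <- function(tape, ll, lh, hl, hh) {
  vs <- list(vof(ll), vof(lh), vof(hl), vof(hh))
  y <- idwtCore(vs[[1]], vs[[2]], vs[[3]], vs[[4]])
  if (is.null(tape)) return(y)
  d <- dim(y)
  adNode(tape, y, function(g) {
    r0 <- seq(1L, d[1], 2L); r1 <- seq(2L, d[1], 2L)
    c0 <- seq(1L, d[2], 2L); c1 <- seq(2L, d[2], 2L)
    g00 <- g[r0, c0, , drop = FALSE]; g01 <- g[r0, c1, , drop = FALSE]
    g10 <- g[r1, c0, , drop = FALSE]; g11 <- g[r1, c1, , drop = FALSE]
    accumGrad(ll, g00 + g01 + g10 + g11)
    accumGrad(lh, g00 - g01 + g10 - g11)
    accumGrad(hl, g00 + g01 - g10 - g11)
    accumGrad(hh, g00 - g01 - g10 + g11)
  })
}

# --- wavelet convolution encoder --------------------------------------------
# One stage: 3x3 conv + BN + ReLU (C -> C'), Haar DWT, 3x3 conv + BN + ReLU on
# the approximation band only (detail bands pass through unchanged), inverse
# DWT, final ReLU. The stage emits both the full-resolution reconstruction
# (the fusion / skip output) and the processed approximation band at half
# resolution, which carries the signal to the next, deeper stage.

initWceBlock <- function(ps, name, cin, cout) {
  initConvBNRelu(ps, paste0(name, ".pre"), 3L, cin, cout)
  initConvBNRelu(ps, paste0(name, ".ll"), 3L, cout, cout)
}

wceBlockForward <- function(ctx, name, x) {
  f <- applyConvBNRelu(ctx, paste0(name, ".pre"), x, 3L)
  d <- dim(vof(f))
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("wavelet stage requires even spatial dimensions, got ",
         d[1], " x ", d[2])
  ll <- opDwtBand(ctx$tape, f, "ll")
  lh <- opDwtBand(ctx$tape, f, "lh")
  hl <- opDwtBand(ctx$tape, f, "hl")
  hh <- opDwtBand(ctx$tape, f, "hh")
  llp <- applyConvBNRelu(ctx, paste0(name, ".ll"), ll, 3L)
  full <- opRelu(ctx$tape, opIdwt(ctx$tape, llp, lh, hl, hh))
  list(full = full, half = llp)
}

# Standard-convolution twin used when the wavelet encoder is ablated: same
# interface (full-resolution output + half-resolution carrier), plain convs.
initWceTwin <- function(ps, name, cin, cout) {
  initConvBNRelu(ps, paste0(name, ".pre"), 3L, cin, cout)
  initConvBNRelu(ps, paste0(name, ".post"), 3L, cout, cout)
}

wceTwinForward <- function(ctx, name, x) {
  f <- applyConvBNRelu(ctx, paste0(name, ".pre"), x, 3L)
  full <- applyConvBNRelu(ctx, paste0(name, ".post"), f, 3L)
  list(full = full, half = opMaxpool2(ctx$tape, full))
}

initWceEncoder <- function(ps, cfg) {
  cp <- cfg$baseChannels
  init <- if (cfg$useWce) initWceBlock else initWceTwin
  init(ps, "wce1", cfg$inChannels, cp)
  init(ps, "wce2", cp, 2L * cp)
  init(ps, "wce3", 2L * cp, 4L * cp)
}

#' @keywords internal
wceEncoderForward <- function(ctx, x) {
  fwd <- if (ctx$cfg$useWce) wceBlockForward else wceTwinForward
  s1 <- fwd(ctx, "wce1", x)
  s2 <- fwd(ctx, "wce2", s1$half)
  s3 <- fwd(ctx, "wce3", s2$half)
  list(s1$full, s2$full, s3$full)
}
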