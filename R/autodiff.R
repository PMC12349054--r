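# Tape-based reverse-mode differentiation.
#
# A tape records nodes in creation order; backward() walks the tape in reverse
# and calls each node's pullback, which accumulates gradients into its parents.
# Nodes are environments holding $value (an array / matrix / scalar), $grad and
# $backfn. Plain arrays mixed into an expression are treated as constants.
# Passing tape = NULL makes every op return its plain value, giving a single
# code path for training and inference.

adTape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

isNode <- function(x) is.environment(x)

vof <- function(x) if (is.environment(x)) x$value else x

adNode <- function(tape, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

adLeaf <- function(tape, value) adNode(tape, value, NULL)

accumGrad <- function(x, g) {
  if (!is.environment(x)) return(invisible(NULL))
  x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible(NULL)
}

adBackward <- function(tape, loss) {
  loss$grad <- 1
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

# --- elementwise and reduction ops -----------------------------------------

opAdd <- function(tape, a, b) {
  y <- vof(a) + vof(b)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) { accumGrad(a, g); accumGrad(b, g) })
}

opSub <- function(tape, a, b) {
  y <- vof(a) - vof(b)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) { accumGrad(a, g); accumGrad(b, -g) })
}

opMul <- function(tape, a, b) {
  av <- vof(a); bv <- vof(b)
  y <- av * bv
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) { accumGrad(a, g * bv); accumGrad(b, g * av) })
}

opDiv <- function(tape, a, b) {
  av <- vof(a); bv <- vof(b)
  y <- av / bv
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    accumGrad(a, g / bv)
    accumGrad(b, -g * av / (bv * bv))
  })
}

opScale <- function(tape, x, k) {
  y <- vof(x) * k
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) accumGrad(x, g * k))
}

opAddConst <- function(tape, x, k) {
  y <- vof(x) + k
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) accumGrad(x, g))
}

opRelu <- function(tape, x) {
  xv <- vof(x)
  y <- pmax(xv, 0)
  if (!is.null(dim(xv))) dim(y) <- dim(xv)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) accumGrad(x, g * (xv > 0)))
}

opSigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-vof(x)))
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) accumGrad(x, g * y * (1 - y)))
}

opLog <- function(tape, x) {
  xv <- vof(x)
  y <- log(xv)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) accumGrad(x, g / xv))
}

opSum <- function(tape, x) {
  xv <- vof(x)
  y <- sum(xv)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) accumGrad(x, array(g, dim(xv) %||% length(xv))))
}

opMean <- function(tape, x) {
  xv <- vof(x)
  n <- length(xv)
  y <- sum(xv) / n
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) accumGrad(x, array(g / n, dim(xv) %||% n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- matrix ops (token sequences) ------------------------------------------

opMatmul <- function(tape, a, b) {
  av <- vof(a); bv <- vof(b)
  y <- av %*% bv
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    accumGrad(a, g %*% t(bv))
    accumGrad(b, t(av) %*% g)
  })
}

opAddRowvec <- function(tape, x, b) {
  # adds a length-ncol vector to every row of a matrix
  xv <- vof(x); bv <- vof(b)
  y <- sweep(xv, 2L, bv, "+")
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    accumGrad(x, g)
    accumGrad(b, colSums(g))
  })
}

opSoftmaxRows <- function(tape, x) {
  xv <- vof(x)
  m <- xv - apply(xv, 1L, max)
  e <- exp(m)
  y <- e / rowSums(e)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    accumGrad(x, (g - rowSums(g * y)) * y)
  })
}

opCbind <- function(tape, a, b) {
  av <- vof(a); bv <- vof(b)
  y <- cbind(av, bv)
  if (is.null(tape)) return(y)
  na <- ncol(av)
  adNode(tape, y, function(g) {
    accumGrad(a, g[, seq_len(na), drop = FALSE])
    accumGrad(b, g[, -seq_len(na), drop = FALSE])
  })
}

# --- spatial ops (H, W, C arrays; C++ kernels) ------------------------------

opConv2d <- function(tape, x, w, b, K, pad = (K - 1L) %/% 2L) {
  xv <- vof(x); wv <- vof(w); bv <- vof(b)
  y <- cpp_conv2d_fwd(xv, wv, bv, K, pad)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    bw <- cpp_conv2d_bwd(xv, wv, g, K, pad)
    accumGrad(x, bw$gx); accumGrad(w, bw$gw); accumGrad(b, bw$gb)
  })
}

opDepthwise <- function(tape, x, w, b, K, pad = (K - 1L) %/% 2L) {
  xv <- vof(x); wv <- vof(w); bv <- vof(b)
  y <- cpp_depthwise_fwd(xv, wv, bv, K, pad)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    bw <- cpp_depthwise_bwd(xv, wv, g, K, pad)
    accumGrad(x, bw$gx); accumGrad(w, bw$gw); accumGrad(b, bw$gb)
  })
}

opDeformConv <- function(tape, x, w, b, off, K, pad = (K - 1L) %/% 2L) {
  xv <- vof(x); wv <- vof(w); bv <- vof(b); ov <- vof(off)
  y <- cpp_deform_fwd(xv, wv, bv, ov, K, pad)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    bw <- cpp_deform_bwd(xv, wv, ov, g, K, pad)
    accumGrad(x, bw$gx); accumGrad(w, bw$gw)
    accumGrad(b, bw$gb); accumGrad(off, bw$goff)
  })
}

opMaxpool2 <- function(tape, x) {
  xv <- vof(x)
  fw <- cpp_maxpool2_fwd(xv)
  if (is.null(tape)) return(fw$y)
  d <- dim(xv)
  adNode(tape, fw$y, function(g) {
    accumGrad(x, cpp_maxpool2_bwd(g, fw$idx, d[1], d[2], d[3]))
  })
}

opResizeBilinear <- function(tape, x, Ho, Wo) {
  xv <- vof(x)
  y <- cpp_resize_bilinear_fwd(xv, Ho, Wo)
  if (is.null(tape)) return(y)
  d <- dim(xv)
  adNode(tape, y, function(g) {
    accumGrad(x, cpp_resize_bilinear_bwd(g, d[1], d[2]))
  })
}

opConcatC <- function(tape, a, b) {
  av <- vof(a); bv <- vof(b)
  da <- dim(av); db <- dim(bv)
  y <- array(c(av, bv), c(da[1], da[2], da[3] + db[3]))
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    accumGrad(a, g[, , seq_len(da[3]), drop = FALSE])
    accumGrad(b, g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# --- batch normalization ----------------------------------------------------
# Statistics over the spatial dims of one image (effective batch size one);
# running averages (held in `state`, a list with mean/var) are used when
# training = FALSE and updated by side effect on the param store when training.

opBatchnorm <- function(tape, x, gamma, beta, state, training,
                        momentum = 0.1, eps = 1e-5, ps = NULL, key = NULL) {
  xv <- vof(x); gv <- vof(gamma); bv <- vof(beta)
  d <- dim(xv)
  n <- d[1] * d[2]
  xm <- matrix(xv, n, d[3])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    if (!is.null(ps)) {
      st <- ps$state[[key]]
      st$mean <- (1 - momentum) * st$mean + momentum * mu
      st$var <- (1 - momentum) * st$var + momentum * va
      ps$state[[key]] <- st
    }
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xm, 2L, mu, "-")
  xhat <- sweep(xhat, 2L, inv, "*")
  ym <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  y <- array(ym, d)
  if (is.null(tape)) return(y)
  adNode(tape, y, function(g) {
    gm <- matrix(g, n, d[3])
    accumGrad(gamma, colSums(gm * xhat))
    accumGrad(beta, colSums(gm))
    gxh <- sweep(gm, 2L, gv, "*")
    if (training) {
      # statistics depend on x
      t1 <- sweep(gxh, 2L, colMeans(gxh), "-")
      t2 <- sweep(xhat, 2L, colMeans(gxh * xhat), "*")
      gx <- sweep(t1 - t2, 2L, inv, "*")
    } else {
      gx <- sweep(gxh, 2L, inv, "*")
    }
    accumGrad(x, array(gx, d))
  })
}
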