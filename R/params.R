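# Parameter store and shared layer helpers.
#
# All trainable arrays live in an environment keyed by hierarchical names
# ("dce1.conv.w", "gft.psi_q_w", ...). A forward pass runs inside a context
# `ctx` carrying the store, an optional autodiff tape and the training flag;
# getLeaf() hands out one tape leaf per parameter so gradients accumulate
# correctly when a parameter is used more than once (shared projections).

newParamStore <- function() {
  ps <- new.env(parent = emptyenv())
  ps$params <- new.env(parent = emptyenv())
  ps$state <- new.env(parent = emptyenv())   # BN running statistics
  ps$order <- character(0)
  ps
}

addParam <- function(ps, name, value) {
  if (!is.null(ps$params[[name]]))
    stop("duplicate parameter name: ", name)
  ps$params[[name]] <- value
  ps$order <- c(ps$order, name)
  invisible(ps)
}

paramVector <- function(ps) {
  unlist(lapply(ps$order, function(nm) as.numeric(ps$params[[nm]])),
         use.names = FALSE)
}

makeCtx <- function(ps, tape = NULL, training = FALSE, cfg = list()) {
  ctx <- new.env(parent = emptyenv())
  ctx$ps <- ps
  ctx$tape <- tape
  ctx$training <- training
  ctx$cfg <- cfg
  ctx$leaves <- new.env(parent = emptyenv())
  ctx
}

getLeaf <- function(ctx, name) {
  p <- ctx$ps$params[[name]]
  if (is.null(p)) stop("unknown parameter: ", name)
  if (is.null(ctx$tape)) return(p)
  lf <- ctx$leaves[[name]]
  if (is.null(lf)) {
    lf <- adLeaf(ctx$tape, p)
    ctx$leaves[[name]] <- lf
  }
  lf
}

# He-normal initialisation for convolutions feeding ReLU units.
heMat <- function(nrow, ncol, fanin) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fanin)), nrow, ncol)
}

xavierMat <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(1 / nrow)), nrow, ncol)
}

# --- dense convolution ------------------------------------------------------

initConv <- function(ps, name, K, cin, cout, zero = FALSE) {
  w <- if (zero) matrix(0, K * K * cin, cout) else
    heMat(K * K * cin, cout, K * K * cin)
  addParam(ps, paste0(name, ".w"), w)
  addParam(ps, paste0(name, ".b"), numeric(cout))
}

applyConv <- function(ctx, name, x, K) {
  opConv2d(ctx$tape, x, getLeaf(ctx, paste0(name, ".w")),
           getLeaf(ctx, paste0(name, ".b")), K)
}

# --- batch normalization ----------------------------------------------------

initBN <- function(ps, name, c) {
  addParam(ps, paste0(name, ".gamma"), rep(1, c))
  addParam(ps, paste0(name, ".beta"), numeric(c))
  ps$state[[name]] <- list(mean = numeric(c), var = rep(1, c))
}

applyBN <- function(ctx, name, x) {
  if (isFALSE(ctx$cfg$useBn)) return(x)
  opBatchnorm(ctx$tape, x,
              getLeaf(ctx, paste0(name, ".gamma")),
              getLeaf(ctx, paste0(name, ".beta")),
              ctx$ps$state[[name]], ctx$training,
              ps = ctx$ps, key = name)
}

initConvBNRelu <- function(ps, name, K, cin, cout, bn = TRUE) {
  initConv(ps, paste0(name, ".conv"), K, cin, cout)
  if (bn) initBN(ps, paste0(name, ".bn"), cout)
}

applyConvBNRelu <- function(ctx, name, x, K) {
  y <- applyConv(ctx, paste0(name, ".conv"), x, K)
  y <- applyBN(ctx, paste0(name, ".bn"), y)
  opRelu(ctx$tape, y)
}

# --- depthwise separable convolution ----------------------------------------

initDSC <- function(ps, name, K, cin, cout) {
  addParam(ps, paste0(name, ".dw"), heMat(K * K, cin, K * K))
  addParam(ps, paste0(name, ".dwb"), numeric(cin))
  initConv(ps, paste0(name, ".pw"), 1L, cin, cout)
}

applyDSC <- function(ctx, name, x, K = 3L) {
  y <- opDepthwise(ctx$tape, x, getLeaf(ctx, paste0(name, ".dw")),
                   getLeaf(ctx, paste0(name, ".dwb")), K)
  applyConv(ctx, paste0(name, ".pw"), y, 1L)
}

# --- token-wise linear layer ------------------------------------------------

initLinear <- function(ps, name, din, dout, xavier = FALSE) {
  w <- if (xavier) xavierMat(din, dout) else heMat(din, dout, din)
  addParam(ps, paste0(name, ".w"), w)
  addParam(ps, paste0(name, ".b"), numeric(dout))
}

applyLinear <- function(ctx, name, x) {
  opAddRowvec(ctx$tape, opMatmul(ctx$tape, x, getLeaf(ctx, paste0(name, ".w"))),
              getLeaf(ctx, paste0(name, ".b")))
}

# RNG scoping: evaluate `code` under a fixed seed, restoring the caller's RNG.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
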