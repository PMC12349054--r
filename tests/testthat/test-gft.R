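test_that("patchify with P = H = W yields one token and inverts exactly", {
  set.seed(31)
  f <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  tk <- patchify(f, 4)
  expect_equal(dim(tk), c(1L, 48L))
  expect_equal(unpatchify(tk, 4, 4, 4), f)
  expect_equal(patchify(array(0, c(4, 4, 2)), 2), matrix(0, 4, 8))
  expect_error(patchify(f, 3), "divide")
})

test_that("patchify round-trips with and without positional parameters", {
  set.seed(32)
  f <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  pos <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  tk <- patchify(f, 2, positional = pos)
  back <- unpatchify(tk, 2, 8, 8)
  # subtracting the broadcast positional correction recovers the input
  posBig <- pos[rep(1:4, each = 2), rep(1:4, each = 2), ]
  expect_equal(back - posBig, f, tolerance = 1e-12)
})

test_that("a single token makes the attention a pure value crossover", {
  set.seed(33)
  D <- 6
  A <- matrix(rnorm(D), 1, D); B <- matrix(rnorm(D), 1, D)
  wts <- lapply(setNames(nm = c("qa", "ka", "va", "qb", "kb", "vb")),
                function(i) matrix(rnorm(D * D), D, D))
  out <- gatedCrossAttention(A, B, wts)
  expect_equal(out$za, B %*% wts$vb)
  expect_equal(out$zb, A %*% wts$va)
  expect_equal(as.numeric(out$attA), 1)
})

test_that("a hard-off gate recovers plain cross-attention", {
  set.seed(34)
  M <- 4; D <- 8
  A <- matrix(rnorm(M * D), M, D); B <- matrix(rnorm(M * D), M, D)
  wts <- lapply(setNames(nm = c("qa", "ka", "va", "qb", "kb", "vb")),
                function(i) matrix(rnorm(D * D, sd = 0.4), D, D))
  # drive the other branch's keys to -Inf: sigmoid -> 0, so the gated keys
  # reduce to the residual K term and the row is plain cross-attention
  kbNeg <- matrix(-1e9, M, D)
  qa <- A %*% wts$qa; ka <- A %*% wts$ka
  att <- wdvessel:::softmaxRows(qa %*% t(ka * stats::plogis(kbNeg) + ka) / sqrt(D))
  plain <- wdvessel:::softmaxRows(qa %*% t(ka) / sqrt(D))
  expect_equal(att, plain, tolerance = 1e-9)
  # gate bounded in (0, 1): gated key norm lies between 1x and 2x plain keys
  gate <- stats::plogis(B %*% wts$kb)
  expect_true(all(gate > 0 & gate < 1))
})

test_that("gated cross-attention matches the literal loop oracle", {
  set.seed(35)
  for (rep in 1:5) {
    M <- 4; D <- 8
    A <- matrix(rnorm(M * D), M, D); B <- matrix(rnorm(M * D), M, D)
    wts <- lapply(setNames(nm = c("qa", "ka", "va", "qb", "kb", "vb")),
                  function(i) matrix(rnorm(D * D, sd = 0.5), D, D))
    got <- gatedCrossAttention(A, B, wts)
    want <- oracleGatedAttention(A, B, wts)
    expect_equal(got$za, want$za, tolerance = 1e-10)
    expect_equal(got$zb, want$zb, tolerance = 1e-10)
    expect_equal(rowSums(got$attA), rep(1, M), tolerance = 1e-6)
    expect_equal(rowSums(got$attB), rep(1, M), tolerance = 1e-6)
  }
})

test_that("the fusion block reduces to its residual when heads are zeroed", {
  net <- vesselNet(inputSize = 32, baseChannels = 4, seed = 9, useBn = FALSE)
  ps <- net@ps
  # zero the MLP output layer and the upsampling projection: the block
  # output must equal the residual carrier exactly
  ps$params[["gft.mlp2.w"]][] <- 0
  ps$params[["gft.mlp2.b"]][] <- 0
  ps$params[["gft.up.w"]][] <- 0
  ps$params[["gft.up.b"]][] <- 0
  ctx <- wdvessel:::makeCtx(ps, NULL, FALSE, net@config)
  c2 <- 32L  # 8 * baseChannels
  fWD <- array(runif(4 * 4 * c2), c(4, 4, c2))
  fDW <- array(runif(4 * 4 * c2), c(4, 4, c2))
  out <- wdvessel:::gftForward(ctx, fWD, fDW)
  expect_equal(out, fWD, tolerance = 1e-12)
})

test_that("the fusion block equals its composed sub-operations", {
  set.seed(36)
  net <- vesselNet(inputSize = 32, baseChannels = 4, seed = 10, useBn = FALSE)
  ps <- net@ps
  ctx <- wdvessel:::makeCtx(ps, NULL, FALSE, net@config)
  c2 <- 32L; P <- 2L
  fWD <- array(runif(4 * 4 * c2), c(4, 4, c2))
  fDW <- array(runif(4 * 4 * c2), c(4, 4, c2))
  got <- wdvessel:::gftForward(ctx, fWD, fDW)
  # manual composition with exported / plain-R pieces
  aW <- patchify(fWD, P, positional = ps$params[["gft.pos_w"]])
  aD <- patchify(fDW, P, positional = ps$params[["gft.pos_d"]])
  wts <- list(qa = ps$params[["gft.psi_qw"]], ka = ps$params[["gft.psi_kw"]],
              va = ps$params[["gft.psi_vw"]], qb = ps$params[["gft.psi_qd"]],
              kb = ps$params[["gft.psi_kd"]], vb = ps$params[["gft.psi_vd"]])
  z <- gatedCrossAttention(aW, aD, wts)
  h <- pmax(sweep(cbind(z$za, z$zb) %*% ps$params[["gft.mlp1.w"]], 2,
                  ps$params[["gft.mlp1.b"]], "+"), 0)
  tok <- sweep(h %*% ps$params[["gft.mlp2.w"]], 2,
               ps$params[["gft.mlp2.b"]], "+")
  grid <- array(tok, c(2, 2, c2))
  up <- wdvessel:::cpp_resize_bilinear_fwd(grid, 4L, 4L)
  proj <- wdvessel:::cpp_conv2d_fwd(up, ps$params[["gft.up.w"]],
                                    ps$params[["gft.up.b"]], 1L, 0L)
  expect_equal(got, proj + fWD, tolerance = 1e-10)
})

test_that("fusion output keeps the carrier shape for all valid patch sizes", {
  for (P in c(1L, 2L, 4L)) {
    net <- vesselNet(inputSize = 64, baseChannels = 2, patchSize = P,
                     seed = 1, useBn = FALSE)
    ctx <- wdvessel:::makeCtx(net@ps, NULL, FALSE, net@config)
    c2 <- 16L
    f <- array(runif(8 * 8 * c2), c(8, 8, c2))
    out <- wdvessel:::gftForward(ctx, f, f)
    expect_equal(dim(out), c(8L, 8L, c2))
  }
})
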