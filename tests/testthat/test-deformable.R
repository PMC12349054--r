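test_that("bilinear sampling collapses to exact reads at integer locations", {
  set.seed(21)
  x <- array(rnorm(5 * 7 * 2), c(5, 7, 2))
  for (rep in 1:5) {
    i <- sample(0:4, 1); j <- sample(0:6, 1)
    expect_equal(as.numeric(bilinearSample(x, c(i, j))), x[i + 1, j + 1, ])
  }
  expect_equal(bilinearSample(matrix(c(0, 2, 1, 3), 2, 2), c(0.5, 0.5)), 1.5)
  expect_error(bilinearSample(x, c(NaN, 1)), "finite")
})

test_that("bilinear sampling matches the four-term weighted-sum oracle", {
  set.seed(22)
  m <- matrix(rnorm(30), 5, 6)
  pts <- cbind(runif(25, -1.5, 5.5), runif(25, -1.5, 6.5))
  got <- bilinearSample(m, pts)
  want <- apply(pts, 1, function(p) oracleBilinear(m, p[1], p[2]))
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
})

test_that("zero offsets reduce deformable convolution to a standard conv", {
  set.seed(23)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- randomWeights(3, 2, 3)
  b <- rnorm(3)
  off <- array(0, c(6, 6, 18))
  expect_equal(deformConv(x, w, off, b), oracleConv(x, w, b),
               tolerance = 1e-12)
})

test_that("constant input under arbitrary offsets gives c * sum(w) inside", {
  set.seed(24)
  cval <- 1.7
  x <- array(cval, c(9, 9, 1))
  w <- randomWeights(3, 1, 2)
  off <- array(runif(9 * 9 * 18, -1, 1), c(9, 9, 18))
  y <- deformConv(x, w, off)
  # interior pixels: every sample (|offset| <= 1, |tap| <= 1) stays in range
  interior <- 3:7
  for (co in 1:2)
    expect_equal(y[interior, interior, co],
                 matrix(cval * sum(w[, , 1, co]), 5, 5), tolerance = 1e-10)
})

test_that("deformable convolution matches the per-pixel per-tap loop oracle", {
  set.seed(25)
  for (rep in 1:3) {
    x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
    w <- randomWeights(3, 2, 2)
    b <- rnorm(2)
    off <- array(rnorm(5 * 5 * 18, sd = 0.8), c(5, 5, 18))
    expect_equal(deformConv(x, w, off, b), oracleDeformConv(x, w, off, b),
                 tolerance = 1e-10)
  }
})

test_that("shifting all offsets by one column samples the shifted input", {
  set.seed(26)
  x <- array(rnorm(8 * 8), c(8, 8, 1))
  w <- randomWeights(3, 1, 1)
  off0 <- array(0, c(8, 8, 18))
  off1 <- off0
  off1[, , seq(2, 18, 2)] <- 1          # constant +1 column displacement
  y1 <- deformConv(x, w, off1)
  xs <- x
  xs[, 1:7, ] <- x[, 2:8, ]             # column-shifted input
  y0 <- deformConv(xs, w, off0)
  # interior pixels see identical samples
  expect_equal(y1[3:6, 3:5, 1], y0[3:6, 3:5, 1], tolerance = 1e-12)
})

test_that("an encoder block with zeroed offset head is two convs + 1x1", {
  set.seed(27)
  net <- vesselNet(inputSize = 32, baseChannels = 4, seed = 5, useBn = FALSE)
  ps <- net@ps
  # the offset head is zero-initialised by design; verify, then compose
  expect_true(all(ps$params[["dce1.off.w"]] == 0))
  x <- array(runif(32 * 32), c(32, 32, 1))
  ctx <- wdvessel:::makeCtx(ps, NULL, FALSE, net@config)
  got <- wdvessel:::dceBlockForward(ctx, "dce1", x)
  ya <- pmax(wdvessel:::cpp_conv2d_fwd(x, ps$params[["dce1.a.conv.w"]],
                                       ps$params[["dce1.a.conv.b"]], 3L, 1L), 0)
  yb <- wdvessel:::cpp_conv2d_fwd(x, ps$params[["dce1.dconv.w"]],
                                  ps$params[["dce1.dconv.b"]], 3L, 1L)
  want <- pmax(wdvessel:::cpp_conv2d_fwd(ya + yb, ps$params[["dce1.proj.w"]],
                                         ps$params[["dce1.proj.b"]], 1L, 0L), 0)
  expect_equal(got, want, tolerance = 1e-12)
  # zero input with zero biases gives zero output
  for (nm in grep("^dce1.*\\.b$", ps$order, value = TRUE))
    ps$params[[nm]][] <- 0
  z <- wdvessel:::dceBlockForward(ctx, "dce1", array(0, c(32, 32, 1)))
  expect_true(max(abs(z)) == 0)
})

test_that("whole deformable encoder with zero offsets matches a conv twin", {
  # the ablation twin replaces the deformable branch by a plain conv; with
  # the offset head zeroed the full encoder must agree with it exactly
  set.seed(28)
  netD <- vesselNet(inputSize = 32, baseChannels = 4, seed = 7, useBn = FALSE)
  netT <- vesselNet(inputSize = 32, baseChannels = 4, seed = 7, useDce = FALSE,
                    useBn = FALSE)
  # graft the deformable net's weights onto the twin (same layer names
  # except the absent offset head)
  for (nm in netT@ps$order)
    if (startsWith(nm, "dce")) netT@ps$params[[nm]] <- netD@ps$params[[nm]]
  x <- array(runif(32 * 32), c(32, 32, 1))
  ctxD <- wdvessel:::makeCtx(netD@ps, NULL, FALSE, netD@config)
  ctxT <- wdvessel:::makeCtx(netT@ps, NULL, FALSE, netT@config)
  sD <- wdvessel:::dceEncoderForward(ctxD, x)
  sT <- wdvessel:::dceEncoderForward(ctxT, x)
  for (k in 1:3) expect_lt(max(abs(sD[[k]] - sT[[k]])), 1e-10)
})

test_that("deformable encoder stages halve extent and double channels", {
  net <- vesselNet(inputSize = 64, baseChannels = 8, seed = 1, useBn = FALSE)
  ctx <- wdvessel:::makeCtx(net@ps, NULL, FALSE, net@config)
  st <- wdvessel:::dceEncoderForward(ctx, array(runif(64 * 64), c(64, 64, 1)))
  expect_equal(dim(st[[1]]), c(64L, 64L, 8L))
  expect_equal(dim(st[[2]]), c(32L, 32L, 16L))
  expect_equal(dim(st[[3]]), c(16L, 16L, 32L))
})

test_that("max pooling selects the single positive pixel in each window", {
  x <- array(0, c(4, 4, 1))
  x[1, 2, 1] <- 3; x[4, 3, 1] <- 5; x[2, 1, 1] <- -1
  # make other entries negative so the positive pixel must win
  x[x == 0] <- -2
  y <- wdvessel:::opMaxpool2(NULL, x)
  expect_equal(y[1, 1, 1], 3)
  expect_equal(y[2, 2, 1], 5)
})
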