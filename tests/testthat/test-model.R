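test_that("construction is deterministic and seed-sensitive", {
  a <- vesselNet(inputSize = 32, baseChannels = 4, seed = 42)
  b <- vesselNet(inputSize = 32, baseChannels = 4, seed = 42)
  c <- vesselNet(inputSize = 32, baseChannels = 4, seed = 43)
  expect_identical(wdvessel:::paramVector(a@ps), wdvessel:::paramVector(b@ps))
  expect_false(identical(wdvessel:::paramVector(a@ps),
                         wdvessel:::paramVector(c@ps)))
})

test_that("invalid configurations fail with the violated constraint named", {
  expect_error(vesselNet(inputSize = 30), "divisible by 8")
  expect_error(vesselNet(inputSize = 64, patchSize = 3), "patchSize")
  expect_error(vesselNet(inputSize = 64, skipMode = "mix"), "skipMode")
})

test_that("forward output is a probability map of the input size", {
  net <- vesselNet(inputSize = 64, baseChannels = 8, seed = 1)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  p <- predictProb(net, img)
  expect_equal(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))
  # zero input stays finite
  expect_true(all(is.finite(predictProb(net, matrix(0, 64, 64)))))
  # wrong size is an explicit error
  expect_error(predictProb(net, matrix(0, 32, 32)), "built for")
})

test_that("every ablation variant builds and runs forward", {
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  for (v in list(list(useWce = FALSE), list(useDce = FALSE),
                 list(useGft = FALSE), list(useDsc = FALSE),
                 list(skipMode = "concat"))) {
    net <- do.call(vesselNet, c(list(inputSize = 64, baseChannels = 4,
                                     seed = 1), v))
    p <- predictProb(net, img)
    expect_equal(dim(p), c(64L, 64L))
    expect_true(all(is.finite(p)))
  }
})

test_that("gradient flows to every trainable parameter", {
  net <- vesselNet(inputSize = 32, baseChannels = 2, seed = 3)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  mask <- matrix(rbinom(32 * 32, 1, 0.15), 32, 32); dim(mask) <- c(32, 32, 1)
  tape <- wdvessel:::adTape()
  out <- wdvessel:::netForward(net, img, tape = tape, training = TRUE)
  loss <- wdvessel:::opCompositeLoss(tape, out$logits, out$prob, mask)
  wdvessel:::adBackward(tape, loss)
  leaves <- out$ctx$leaves
  touched <- vapply(net@ps$order, function(nm) !is.null(leaves[[nm]]$grad),
                    logical(1))
  expect_true(all(touched))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(51)
  net <- vesselNet(inputSize = 32, baseChannels = 2, seed = 3)
  ps <- net@ps
  # move the offset head off the integer-grid kink where the bilinear read
  # is not differentiable
  ps$params[["dce1.off.b"]][] <- runif(18, -0.3, 0.3)
  ps$params[["dce2.off.b"]][] <- runif(18, -0.3, 0.3)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  mask <- matrix(rbinom(32 * 32, 1, 0.15), 32, 32); dim(mask) <- c(32, 32, 1)
  lossAt <- function() {
    tape <- wdvessel:::adTape()
    out <- wdvessel:::netForward(net, img, tape = tape, training = TRUE)
    list(tape = tape, out = out,
         loss = wdvessel:::opCompositeLoss(tape, out$logits, out$prob, mask))
  }
  r <- lossAt()
  wdvessel:::adBackward(r$tape, r$loss)
  for (nm in c("wce1.pre.conv.w", "wce2.ll.bn.gamma", "dce1.off.b",
               "dce2.dconv.w", "gft.psi_kw", "gft.pos_d", "dec3.dsc.dw",
               "dec1.out.b", "fuse3.w")) {
    g <- r$out$ctx$leaves[[nm]]$grad
    k <- sample(length(ps$params[[nm]]), 1)
    eps <- 1e-5
    old <- ps$params[[nm]][k]
    ps$params[[nm]][k] <- old + eps; lp <- wdvessel:::vof(lossAt()$loss)
    ps$params[[nm]][k] <- old - eps; lm <- wdvessel:::vof(lossAt()$loss)
    ps$params[[nm]][k] <- old
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - g[k]) / max(1e-6, abs(fd) + abs(g[k])), 1e-3)
  }
})

test_that("composite loss obeys its closed forms and a loop oracle", {
  # matching prediction drives the loss to zero in the saturation limit
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  for (eps in c(1e-3, 1e-5)) {
    p <- abs(m - eps)
    expect_lt(compositeLoss(p, m), compositeLoss(abs(m - 1e-2), m) + 1e-12)
  }
  expect_lt(compositeLoss(abs(m - 1e-7), m), 1e-5)
  # flat 0.5 prediction: the BCE term is exactly log(2)
  p5 <- matrix(0.5, 8, 8)
  dice5 <- (2 * sum(0.5 * m) + 1) / (sum(p5) + sum(m) + 1)
  expect_equal(compositeLoss(p5, m), log(2) + 1 - dice5, tolerance = 1e-12)
  # random case against an independent scalar loop
  set.seed(52)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  bce <- 0
  for (i in 1:8) for (j in 1:8)
    bce <- bce - (m[i, j] * log(p[i, j]) + (1 - m[i, j]) * log(1 - p[i, j]))
  bce <- bce / 64
  inter <- 0; sp <- 0; sm <- 0
  for (i in 1:8) for (j in 1:8) {
    inter <- inter + p[i, j] * m[i, j]; sp <- sp + p[i, j]; sm <- sm + m[i, j]
  }
  want <- bce + 1 - (2 * inter + 1) / (sp + sm + 1)
  expect_equal(compositeLoss(p, m), want, tolerance = 1e-10)
  expect_error(compositeLoss(p, m[1:4, 1:4]), "shape")
})

test_that("parameter report is exact and monotone under ablation", {
  # a single 3x3 conv with bias, 1 -> 8 channels: 9*8 + 8 = 80
  ps <- wdvessel:::newParamStore()
  wdvessel:::initConv(ps, "c", 3L, 1L, 8L)
  expect_identical(sum(vapply(ps$order, function(nm)
    length(ps$params[[nm]]), integer(1))), 80L)
  net <- vesselNet(inputSize = 32, baseChannels = 4, seed = 1)
  cp <- countParams(net)
  expect_equal(cp$total,
               sum(vapply(net@ps$order, function(nm)
                 length(net@ps$params[[nm]]), integer(1))))
})

test_that("checkpoints reproduce the model bit for bit", {
  net <- vesselNet(inputSize = 32, baseChannels = 4, seed = 6)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  f <- tempfile(fileext = ".ckpt")
  saveCheckpoint(net, f)
  net2 <- loadCheckpoint(f)
  expect_identical(wdvessel:::paramVector(net@ps),
                   wdvessel:::paramVector(net2@ps))
  expect_identical(predictProb(net, img), predictProb(net2, img))
})
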