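# Independent brute-force oracles used across the suite. These are written
# as literal per-element loops, deliberately sharing no code with the
# package's vectorized / compiled implementations.

# Haar analysis of one channel, block by block
oracleDWT <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ll <- lh <- hl <- hh <- matrix(0, H / 2, W / 2)
  for (i in seq_len(H / 2)) for (j in seq_len(W / 2)) {
    F00 <- m[2 * i - 1, 2 * j - 1]; F01 <- m[2 * i - 1, 2 * j]
    F10 <- m[2 * i, 2 * j - 1];     F11 <- m[2 * i, 2 * j]
    ll[i, j] <- (F00 + F01 + F10 + F11) / 4
    lh[i, j] <- (F00 - F01 + F10 - F11) / 4
    hl[i, j] <- (F00 + F01 - F10 - F11) / 4
    hh[i, j] <- (F00 - F01 - F10 + F11) / 4
  }
  list(ll = ll, lh = lh, hl = hl, hh = hh)
}

oracleIDWT <- function(ll, lh, hl, hh) {
  h <- nrow(ll); w <- ncol(ll)
  y <- matrix(0, 2 * h, 2 * w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    y[2 * i - 1, 2 * j - 1] <- ll[i, j] + lh[i, j] + hl[i, j] + hh[i, j]
    y[2 * i - 1, 2 * j]     <- ll[i, j] - lh[i, j] + hl[i, j] - hh[i, j]
    y[2 * i, 2 * j - 1]     <- ll[i, j] + lh[i, j] - hl[i, j] - hh[i, j]
    y[2 * i, 2 * j]         <- ll[i, j] - lh[i, j] - hl[i, j] + hh[i, j]
  }
  y
}

# four-term bilinear read with zero border, 0-based coordinates
oracleBilinear <- function(m, p, q) {
  H <- nrow(m); W <- ncol(m)
  i0 <- floor(p); j0 <- floor(q)
  fy <- p - i0; fx <- q - j0
  v <- 0
  for (di in 0:1) for (dj in 0:1) {
    ii <- i0 + di; jj <- j0 + dj
    if (ii < 0 || ii >= H || jj < 0 || jj >= W) next
    wt <- (if (di) fy else 1 - fy) * (if (dj) fx else 1 - fx)
    v <- v + wt * m[ii + 1, jj + 1]
  }
  v
}

# deformable convolution as a per-pixel per-tap loop
oracleDeformConv <- function(x, w, off, bias) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  K <- dim(w)[1]; cout <- dim(w)[4]
  pad <- (K - 1) / 2
  y <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- bias[co]
    for (kw in seq_len(K)) for (kh in seq_len(K)) {
      t0 <- (kh - 1) + K * (kw - 1)          # 0-based tap index
      dy <- off[i, j, 2 * t0 + 1]; dx <- off[i, j, 2 * t0 + 2]
      p <- (i - 1) + (kh - 1) - pad + dy
      q <- (j - 1) + (kw - 1) - pad + dx
      for (ci in seq_len(cin))
        acc <- acc + w[kh, kw, ci, co] * oracleBilinear(x[, , ci], p, q)
    }
    y[i, j, co] <- acc
  }
  y
}

# dense 2-D convolution (cross-correlation, zero padding) as loops
oracleConv <- function(x, w, bias) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  K <- dim(w)[1]; cout <- dim(w)[4]
  pad <- (K - 1) / 2
  y <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- bias[co]
    for (ci in seq_len(cin)) for (kh in seq_len(K)) for (kw in seq_len(K)) {
      ii <- i + kh - 1 - pad; jj <- j + kw - 1 - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + w[kh, kw, ci, co] * x[ii, jj, ci]
    }
    y[i, j, co] <- acc
  }
  y
}

# depthwise then pointwise, as two explicit loops
oracleDSC <- function(x, dw, pw, bd, bp) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  K <- dim(dw)[1]; pad <- (K - 1) / 2
  mid <- array(0, c(H, W, cin))
  for (c in seq_len(cin)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- bd[c]
    for (kh in seq_len(K)) for (kw in seq_len(K)) {
      ii <- i + kh - 1 - pad; jj <- j + kw - 1 - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + dw[kh, kw, c] * x[ii, jj, c]
    }
    mid[i, j, c] <- acc
  }
  cout <- nrow(pw)
  y <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) for (i in seq_len(H)) for (j in seq_len(W))
    y[i, j, co] <- bp[co] + sum(pw[co, ] * mid[i, j, ])
  y
}

# gated cross-attention as a literal scalar loop over tokens
oracleGatedAttention <- function(A, B, wts) {
  M <- nrow(A); D <- ncol(A)
  qa <- A %*% wts$qa; ka <- A %*% wts$ka; va <- A %*% wts$va
  qb <- B %*% wts$qb; kb <- B %*% wts$kb; vb <- B %*% wts$vb
  za <- matrix(0, M, D); zb <- matrix(0, M, D)
  for (m in seq_len(M)) {
    sa <- numeric(M); sb <- numeric(M)
    for (k in seq_len(M)) {
      kga <- ka[k, ] * (1 / (1 + exp(-kb[k, ]))) + ka[k, ]
      kgb <- kb[k, ] * (1 / (1 + exp(-ka[k, ]))) + kb[k, ]
      sa[k] <- sum(qa[m, ] * kga) / sqrt(D)
      sb[k] <- sum(qb[m, ] * kgb) / sqrt(D)
    }
    pa <- exp(sa - max(sa)); pa <- pa / sum(pa)
    pb <- exp(sb - max(sb)); pb <- pb / sum(pb)
    for (k in seq_len(M)) {
      za[m, ] <- za[m, ] + pa[k] * vb[k, ]
      zb[m, ] <- zb[m, ] + pb[k] * va[k, ]
    }
  }
  list(za = za, zb = zb)
}

# AUC as the O(n^2) pairwise ranking probability with half credit for ties
oracleAUC <- function(score, truth) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

randomWeights <- function(K, cin, cout, sd = 0.3)
  array(rnorm(K * K * cin * cout, sd = sd), c(K, K, cin, cout))

makeRecords <- function(n, seeds = seq_len(n)) {
  lapply(seeds, function(i) {
    ph <- generatePhantom(smallPhantomConfig(seed = i))
    preprocessRecord(list(image = phantomImage(ph), mask = phantomMask(ph),
                          id = paste0("ph", i)))
  })
}
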