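# Correctness of the hand-written layer primitives against independent
# oracles (naive convolution loops, central finite differences).

naive_conv <- function(x, w, stride, pad) {
  d <- dim(x); wd <- dim(w)
  H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]; k <- wd[1]; Cout <- wd[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, N, Cout))
  for (n in 1:N) for (co in 1:Cout) for (oi in 1:Ho) for (oj in 1:Wo) {
    acc <- 0
    for (ci in 1:Cin) for (ki in 1:k) for (kj in 1:k) {
      i <- (oi - 1) * stride + ki - pad
      j <- (oj - 1) * stride + kj - pad
      if (i >= 1 && i <= H && j >= 1 && j <= W) {
        acc <- acc + x[i, j, n, ci] * w[ki, kj, ci, co]
      }
    }
    y[oi, oj, n, co] <- acc
  }
  y
}

test_that("the convolution kernel matches a naive loop oracle", {
  set.seed(41)
  for (case in list(list(k = 3L, s = 1L), list(k = 3L, s = 2L),
                    list(k = 5L, s = 2L), list(k = 1L, s = 1L))) {
    x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
    w <- array(rnorm(case$k^2 * 3 * 4), c(case$k, case$k, 3, 4))
    pad <- (case$k - 1L) %/% 2L
    expect_equal(patchboost:::conv2d_fwd_cpp(x, w, case$s, pad),
                 naive_conv(x, w, case$s, pad), tolerance = 1e-12)
  }
})

test_that("depthwise convolution matches a per-channel conv oracle", {
  set.seed(42)
  x <- array(rnorm(7 * 7 * 2 * 3), c(7, 7, 2, 3))
  w <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  got <- patchboost:::dwconv2d_fwd_cpp(x, w, 1L, 2L)
  for (c in 1:3) {
    wc <- array(0, c(5, 5, 1, 1)); wc[, , 1, 1] <- w[, , c]
    expect_equal(got[, , , c, drop = FALSE],
                 naive_conv(x[, , , c, drop = FALSE], wc, 1L, 2L),
                 tolerance = 1e-12)
  }
})

test_that("convolution backward passes agree with finite differences", {
  set.seed(43)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  dy <- patchboost:::conv2d_fwd_cpp(x, w, 2L, 1L)
  dy[] <- rnorm(length(dy))
  bw <- patchboost:::conv2d_bwd_cpp(x, w, dy, 2L, 1L)
  eps <- 1e-6
  for (i in sample(seq_along(w), 10)) {
    w1 <- w; w1[i] <- w[i] + eps
    w2 <- w; w2[i] <- w[i] - eps
    ng <- (sum(patchboost:::conv2d_fwd_cpp(x, w1, 2L, 1L) * dy) -
           sum(patchboost:::conv2d_fwd_cpp(x, w2, 2L, 1L) * dy)) / (2 * eps)
    expect_equal(bw$dw[i], ng, tolerance = 1e-5)
  }
  for (i in sample(seq_along(x), 10)) {
    x1 <- x; x1[i] <- x[i] + eps
    x2 <- x; x2[i] <- x[i] - eps
    ng <- (sum(patchboost:::conv2d_fwd_cpp(x1, w, 2L, 1L) * dy) -
           sum(patchboost:::conv2d_fwd_cpp(x2, w, 2L, 1L) * dy)) / (2 * eps)
    expect_equal(bw$dx[i], ng, tolerance = 1e-5)
  }
})

test_that("an entire MBConv block backpropagates exactly", {
  set.seed(44)
  bl <- patchboost:::new_mbconv(3L, 5L, 3L, 2L, 3L)
  fc <- patchboost:::new_dense(5L, 2L)
  x <- array(rnorm(8 * 8 * 3 * 3), c(8, 8, 3, 3))
  y <- c(1L, 2L, 1L)
  loss_of <- function(bl) {
    r <- patchboost:::mbconv_fwd(bl, x, TRUE)
    l <- patchboost:::dense_fwd(fc, patchboost:::gap_fwd(r$y)$y)
    patchboost:::softmax_ce(l$y, y)$loss
  }
  r <- patchboost:::mbconv_fwd(bl, x, TRUE)
  p <- patchboost:::gap_fwd(r$y)
  l <- patchboost:::dense_fwd(fc, p$y)
  ce <- patchboost:::softmax_ce(l$y, y)
  db <- patchboost:::dense_bwd(fc, l$cache, ce$dlogits)
  gb <- patchboost:::mbconv_bwd(bl, r$cache,
                                patchboost:::gap_bwd(p$cache, db$dx))
  eps <- 1e-6
  check <- function(get, set, gval, k = 4) {
    p0 <- get(bl)
    for (i in sample(seq_along(p0), min(k, length(p0)))) {
      b1 <- set(bl, replace(p0, i, p0[i] + eps))
      b2 <- set(bl, replace(p0, i, p0[i] - eps))
      ng <- (loss_of(b1) - loss_of(b2)) / (2 * eps)
      expect_equal(gval[i], ng, tolerance = 1e-4)
    }
  }
  check(function(b) b$dw$W,
        function(b, v) { b$dw$W <- array(v, dim(b$dw$W)); b }, gb$g$dw$W)
  check(function(b) b$project$W,
        function(b, v) { b$project$W <- array(v, dim(b$project$W)); b },
        gb$g$project$W)
  check(function(b) b$se$W1,
        function(b, v) { b$se$W1 <- matrix(v, nrow(b$se$W1)); b },
        gb$g$se$W1)
  check(function(b) b$bn1$gamma,
        function(b, v) { b$bn1$gamma <- v; b }, gb$g$bn1$gamma)
  check(function(b) b$bn2$beta,
        function(b, v) { b$bn2$beta <- v; b }, gb$g$bn2$beta)
})

test_that("batch norm switches between batch and running statistics", {
  set.seed(45)
  l <- patchboost:::new_bn(3L)
  x <- array(rnorm(4 * 4 * 2 * 3, mean = 2, sd = 3), c(4, 4, 2, 3))
  tr <- patchboost:::bn_fwd(l, x, training = TRUE)
  m <- matrix(tr$y, ncol = 3)
  expect_equal(colMeans(m), rep(0, 3), tolerance = 1e-12)
  # eval mode uses the (initial) running stats, not the batch stats
  ev <- patchboost:::bn_fwd(l, x, training = FALSE)
  expect_false(isTRUE(all.equal(ev$y, tr$y)))
  # running stats moved toward the batch stats
  expect_false(isTRUE(all.equal(tr$layer$rmean, l$rmean)))
})

test_that("the softmax cross-entropy gradient is exact", {
  set.seed(46)
  logits <- matrix(rnorm(8), 4, 2)
  y <- c(1L, 2L, 2L, 1L)
  ce <- patchboost:::softmax_ce(logits, y)
  eps <- 1e-6
  for (i in seq_along(logits)) {
    l1 <- logits; l1[i] <- l1[i] + eps
    l2 <- logits; l2[i] <- l2[i] - eps
    ng <- (patchboost:::softmax_ce(l1, y)$loss -
           patchboost:::softmax_ce(l2, y)$loss) / (2 * eps)
    expect_equal(ce$dlogits[i], ng, tolerance = 1e-6)
  }
})
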