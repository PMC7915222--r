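# Internal neural-network layers. All feature batches use the layout
# (H, W, N, C); parameter leaves are named W, b, gamma, beta so that the
# optimizer can walk model/gradient trees generically (running batch-norm
# statistics use other names and are never updated by gradients).

PARAM_NAMES <- c("W", "b", "gamma", "beta", "W1", "b1", "W2", "b2")

new_conv <- function(k, cin, cout, stride = 1L) {
  list(W = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 dim = c(k, k, cin, cout)),
       stride = as.integer(stride), pad = (k - 1L) %/% 2L)
}

conv_fwd <- function(l, x) {
  list(y = conv2d_fwd_cpp(x, l$W, l$stride, l$pad), cache = x)
}

conv_bwd <- function(l, cache, dy) {
  r <- conv2d_bwd_cpp(cache, l$W, dy, l$stride, l$pad)
  list(dx = r$dx, g = list(W = r$dw))
}

new_dwconv <- function(k, C, stride = 1L) {
  list(W = array(stats::rnorm(k * k * C, sd = sqrt(2 / (k * k))),
                 dim = c(k, k, C)),
       stride = as.integer(stride), pad = (k - 1L) %/% 2L)
}

dwconv_fwd <- function(l, x) {
  list(y = dwconv2d_fwd_cpp(x, l$W, l$stride, l$pad), cache = x)
}

dwconv_bwd <- function(l, cache, dy) {
  r <- dwconv2d_bwd_cpp(cache, l$W, dy, l$stride, l$pad)
  list(dx = r$dx, g = list(W = r$dw))
}

new_bn <- function(C, momentum = 0.9, eps = 1e-3) {
  list(gamma = rep(1, C), beta = rep(0, C),
       rmean = rep(0, C), rvar = rep(1, C),
       momentum = momentum, eps = eps)
}

bn_fwd <- function(l, x, training) {
  d <- dim(x)
  C <- d[4L]
  if (training) {
    st <- bn_stats_cpp(x, C)
    mu <- st$mu
    v <- st$var
    l$rmean <- l$momentum * l$rmean + (1 - l$momentum) * mu
    l$rvar <- l$momentum * l$rvar + (1 - l$momentum) * v
  } else {
    mu <- l$rmean
    v <- l$rvar
  }
  inv <- 1 / sqrt(v + l$eps)
  ap <- bn_apply_cpp(x, mu, inv, l$gamma, l$beta)
  list(y = ap$y, cache = list(xhat = ap$xhat, inv = inv, d = d,
                              training = training),
       layer = l)
}

bn_bwd <- function(l, cache, dy) {
  r <- bn_bwd_cpp(dy, cache$xhat, l$gamma * cache$inv, cache$training)
  list(dx = r$dx, g = list(gamma = r$dgamma, beta = r$dbeta))
}

swish_fwd <- function(x) {
  r <- swish_fwd_cpp(x)
  list(y = r$y, cache = list(x = x, s = r$s))
}

swish_bwd <- function(cache, dy) {
  swish_bwd_cpp(cache$x, cache$s, dy)
}

new_dense <- function(cin, cout, sd = sqrt(2 / cin)) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sd), cin, cout),
       b = rep(0, cout))
}

dense_fwd <- function(l, x) {
  list(y = sweep_add_rows(x %*% l$W, l$b), cache = x)
}

dense_bwd <- function(l, cache, dy) {
  list(dx = dy %*% t(l$W),
       g = list(W = crossprod(cache, dy), b = colSums(dy)))
}

sweep_add_rows <- function(m, b) m + rep(b, each = nrow(m))

# Global average pooling (H, W, N, C) -> (N, C)
gap_fwd <- function(x) {
  d <- dim(x)
  p <- block_means_cpp(x, d[1L] * d[2L])
  dim(p) <- d[3:4]
  list(y = p, cache = d)
}

gap_bwd <- function(d, dp) {
  dx <- chan_expand_cpp(as.numeric(dp), d[1L] * d[2L])
  dim(dx) <- d
  dx
}

# Multiply every channel of x (H, W, N, C) by the scalar s[n, c].
chan_scale <- function(x, s) {
  d <- dim(x)
  chan_scale_cpp(x, as.numeric(s), d[1L] * d[2L])
}

# Sum of x * dy over the spatial dimensions -> (N, C); the gradient of
# chan_scale with respect to s.
chan_scale_ds <- function(x, dy) {
  d <- dim(x)
  ds <- chan_dot_cpp(x, dy, d[1L] * d[2L])
  dim(ds) <- d[3:4]
  ds
}

# Squeeze-and-excitation sub-block as used inside MBConv blocks:
# pool -> FC (swish) -> FC (sigmoid) -> channel rescale. Biased FCs,
# swish hidden nonlinearity (the backbone's native convention).
new_se <- function(C, cse) {
  list(W1 = matrix(stats::rnorm(C * cse, sd = sqrt(2 / C)), C, cse),
       b1 = rep(0, cse),
       W2 = matrix(stats::rnorm(cse * C, sd = sqrt(2 / cse)), cse, C),
       b2 = rep(0, C))
}

se_fwd <- function(l, x) {
  pz <- gap_fwd(x)
  z <- pz$y
  h <- sweep_add_rows(z %*% l$W1, l$b1)
  hs <- swish_fwd(h)
  a <- sweep_add_rows(hs$y %*% l$W2, l$b2)
  s <- stats::plogis(a)
  list(y = chan_scale(x, s),
       cache = list(x = x, z = z, hs = hs, s = s, d = pz$cache))
}

se_bwd <- function(l, cache, dy) {
  dx <- chan_scale(dy, cache$s)
  ds <- chan_scale_ds(cache$x, dy)
  da <- ds * cache$s * (1 - cache$s)
  dhs <- da %*% t(l$W2)
  dh <- swish_bwd(cache$hs$cache, dhs)
  dz <- dh %*% t(l$W1)
  dx <- dx + gap_bwd(cache$d, dz)
  list(dx = dx,
       g = list(W1 = crossprod(cache$z, dh), b1 = colSums(dh),
                W2 = crossprod(cache$hs$y, da), b2 = colSums(da)))
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

# Mean cross-entropy over the batch; y is a 1-based class index vector.
softmax_ce <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dl <- p
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dl / n)
}

# ---- generic trees of parameters -------------------------------------------

# Walk a gradient tree (lists of lists with numeric leaves) alongside the
# model and the Adam moment trees, returning updated copies.
adam_tree <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (!is.list(g)) {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g * g
    p2 <- p - lr * (m2 / (1 - b1^t)) / (sqrt(v2 / (1 - b2^t)) + eps)
    return(list(p = p2, m = m2, v = v2))
  }
  for (nm in names(g)) {
    r <- adam_tree(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, b1, b2, eps, t)
    p[[nm]] <- r$p
    m[[nm]] <- r$m
    v[[nm]] <- r$v
  }
  list(p = p, m = m, v = v)
}

tree_zero <- function(g) {
  if (!is.list(g)) return(g * 0)
  lapply(g, tree_zero)
}
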