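#' Squeeze: per-channel global average pooling
#'
#' Collapses a feature map `U` of shape `(H, W, C)` to a length-`C` vector
#' whose c-th entry is the mean of channel c over all spatial positions —
#' the "squeeze" half of a squeeze-and-excitation block, giving every
#' channel a global receptive field.
#'
#' @param U Numeric array `(H, W, C)` with `H, W, C >= 1`.
#' @return Numeric vector of length `C`.
#' @export
squeeze <- function(U) {
  d <- dim(U)
  if (is.null(d) || length(d) != 3L || any(d < 1L) || length(U) == 0L) {
    stop("U must be a non-empty (H, W, C) array")
  }
  colMeans(matrix(U, nrow = d[1L] * d[2L]))
}

#' Gate parameters for the excitation step
#'
#' Creates the two fully connected weight matrices of an excitation gate
#' for a `C`-channel map: `W1` maps `C` channels to a hidden width of
#' `C / r` (clamped below at 8, or at `C` when the map is narrower than 8
#' channels) and `W2` maps back to `C`. The reduction ratio of `r` = 16
#' follows the original squeeze-and-excitation design. Weights are drawn
#' from the current RNG stream (He-scaled normal).
#'
#' @param C Channel count.
#' @param r Reduction ratio (positive integer).
#' @return A list of class `"patchboost_gate"` with `W1` (`hidden x C`),
#'   `W2` (`C x hidden`) and `r`.
#' @export
gate_params <- function(C, r = 16L) {
  C <- as.integer(C)
  if (C < 1L) stop("C must be >= 1")
  hidden <- gate_hidden_width(C, r)
  structure(list(
    W1 = matrix(stats::rnorm(hidden * C, sd = sqrt(2 / C)), hidden, C),
    W2 = matrix(stats::rnorm(C * hidden, sd = sqrt(2 / hidden)), C, hidden),
    r = as.integer(r)), class = "patchboost_gate")
}

#' Excite: learn per-channel weights from the squeezed vector
#'
#' The excitation step of a squeeze-and-excitation block:
#' `S = sigmoid(W2 %*% relu(W1 %*% Z))`. The sigmoid keeps every weight
#' strictly inside (0, 1).
#'
#' @param Z Numeric vector of length `C` (the output of [squeeze()]).
#' @param params A gate from [gate_params()], or any list with conformable
#'   `W1` and `W2`.
#' @return Numeric vector of channel weights, each in (0, 1).
#' @export
excite <- function(Z, params) {
  Z <- as.numeric(Z)
  if (ncol(params$W1) != length(Z) || ncol(params$W2) != nrow(params$W1) ||
      nrow(params$W2) != length(Z)) {
    stop("gate shapes not conformable with length(Z) = ", length(Z))
  }
  h <- pmax(params$W1 %*% Z, 0)
  as.vector(stats::plogis(params$W2 %*% h))
}

#' Apply channel attention weights to a feature map
#'
#' Multiplies every spatial position of channel c by `S[c]`; the shape of
#' `U` is unchanged.
#'
#' @param U Numeric array `(H, W, C)`.
#' @param S Numeric vector of length `C`.
#' @return Array of the same shape as `U`.
#' @export
apply_attention <- function(U, S) {
  d <- dim(U)
  if (is.null(d) || length(d) != 3L) stop("U must be a (H, W, C) array")
  if (length(S) != d[3L]) {
    stop("length(S) = ", length(S), " does not match C = ", d[3L])
  }
  y <- matrix(U, nrow = d[1L] * d[2L]) * rep(as.numeric(S), each = d[1L] * d[2L])
  dim(y) <- d
  y
}

#' Fuse tapped and final feature maps into one feature vector
#'
#' The feature-fusion head: each tapped (low-level) map and the final
#' (high-level) map is optionally attention-gated
#' ([squeeze()] / [excite()] / [apply_attention()]), then globally
#' average-pooled to a channel vector; the vectors are concatenated in tap
#' order with the final map's vector last. The fused length is the sum of
#' all channel counts, independent of the spatial sizes.
#'
#' @param tapped Non-empty list of `(H, W, C_i)` arrays.
#' @param final A `(H, W, C)` array.
#' @param attention_on If `TRUE`, gate every map before pooling.
#' @param gates List of gates (one per tapped map, then one for the final
#'   map); required when `attention_on`.
#' @return Numeric vector of length `sum(C_i) + C`.
#' @export
fuse_features <- function(tapped, final, attention_on = FALSE, gates = NULL) {
  if (!is.list(tapped) || length(tapped) == 0L) {
    stop("tapped must be a non-empty list of feature maps")
  }
  maps <- c(tapped, list(final))
  if (attention_on) {
    if (is.null(gates) || length(gates) != length(maps)) {
      stop("attention_on requires one gate per tapped map plus one for the ",
           "final map (", length(maps), " total)")
    }
    maps <- lapply(seq_along(maps), function(i) {
      apply_attention(maps[[i]], excite(squeeze(maps[[i]]), gates[[i]]))
    })
  }
  unlist(lapply(maps, squeeze), use.names = FALSE)
}

# ---- batched gate (internal, used by the fusion head) ----------------------
# Same computation as squeeze/excite/apply_attention but over an
# (H, W, N, C) batch, with the backward pass needed for training.

gate_fwd <- function(l, x) {
  pz <- gap_fwd(x)
  z <- pz$y                       # (N, C)
  h <- z %*% t(l$W1)              # (N, hidden)
  hr <- pmax(h, 0)
  a <- hr %*% t(l$W2)             # (N, C)
  s <- stats::plogis(a)
  list(y = chan_scale(x, s),
       cache = list(x = x, z = z, h = h, hr = hr, s = s, d = pz$cache))
}

gate_bwd <- function(l, cache, dy) {
  dx <- chan_scale(dy, cache$s)
  ds <- chan_scale_ds(cache$x, dy)
  da <- ds * cache$s * (1 - cache$s)
  dhr <- da %*% l$W2
  dh <- dhr * (cache$h > 0)
  dz <- dh %*% l$W1
  dx <- dx + gap_bwd(cache$d, dz)
  list(dx = dx,
       g = list(W1 = crossprod(dh, cache$z), W2 = crossprod(da, cache$hr)))
}
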