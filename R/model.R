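#' Model configuration for the boosted backbone
#'
#' Assembles the configuration for [build_backbone()]: which size preset to
#' use, which of the four boosting strategies to enable, where to tap
#' intermediate block outputs for feature fusion, and the seed for weight
#' initialization.
#'
#' @param preset `"b3"` for the EfficientNet-B3 topology (26 MBConv blocks,
#'   stem width 40, head width 1536) or `"tiny"`, a reduced-width preset with
#'   the same 26-block topology, kernel sizes and stride pattern, small
#'   enough to train on a CPU.
#' @param rcc,rds,ff,attention Logical flags for the four strategies:
#'   random center cropping (a training-time augmentation, recorded here so
#'   a configuration row fully describes an ablation run), reduced
#'   downsampling scale (stem stride 2 to 1), feature fusion over tapped
#'   blocks, and squeeze-and-excitation gates on the fused maps.
#' @param tap_indices 1-based indices into the MBConv block sequence whose
#'   outputs are fused; default `c(4, 7, 17, 25)`. Must be strictly
#'   increasing and at most the block count (26).
#' @param num_classes Number of output classes (default 2).
#' @param seed Integer seed for weight initialization.
#' @return A list of class `"patchboost_config"`.
#' @export
model_config <- function(preset = c("tiny", "b3"), rcc = FALSE, rds = FALSE,
                         ff = FALSE, attention = FALSE,
                         tap_indices = c(4L, 7L, 17L, 25L),
                         num_classes = 2L, seed = 1L) {
  preset <- match.arg(preset)
  tap_indices <- as.integer(tap_indices)
  if (length(tap_indices) > 0L) {
    if (any(diff(tap_indices) <= 0L)) {
      stop("tap_indices must be strictly increasing")
    }
    nb <- sum(backbone_spec(preset)$depths)
    if (any(tap_indices < 1L) || any(tap_indices > nb)) {
      stop("tap_indices must lie in [1, ", nb, "] for preset '", preset, "'")
    }
  }
  structure(list(preset = preset, rcc = isTRUE(rcc), rds = isTRUE(rds),
                 ff = isTRUE(ff), attention = isTRUE(attention),
                 tap_indices = tap_indices,
                 num_classes = as.integer(num_classes),
                 seed = as.integer(seed)),
            class = "patchboost_config")
}

# Stage table of the backbone. "b3" is the EfficientNet-B3 compound scaling
# of the B0 stage layout (width x1.2, depth x1.4): 26 MBConv blocks. "tiny"
# keeps depths, kernels and strides (so all tap indices and spatial
# arithmetic are identical) but shrinks widths and expansion so the full
# code path trains quickly on one CPU.
backbone_spec <- function(preset) {
  switch(preset,
    b3 = list(stem = 40L, channels = c(24L, 32L, 48L, 96L, 136L, 232L, 384L),
              depths = c(2L, 3L, 3L, 5L, 5L, 6L, 2L),
              expand = c(1L, 6L, 6L, 6L, 6L, 6L, 6L),
              kernels = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
              strides = c(1L, 2L, 2L, 2L, 1L, 2L, 1L),
              head = 1536L),
    tiny = list(stem = 6L, channels = c(6L, 6L, 12L, 12L, 16L, 16L, 24L),
                depths = c(2L, 3L, 3L, 5L, 5L, 6L, 2L),
                expand = c(1L, 2L, 2L, 2L, 2L, 2L, 2L),
                kernels = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
                strides = c(1L, 2L, 2L, 2L, 1L, 2L, 1L),
                head = 48L),
    stop("unknown preset: ", preset)
  )
}

new_mbconv <- function(cin, cout, k, stride, expand, se_ratio = 0.25) {
  ce <- cin * expand
  bl <- list(cin = cin, cout = cout, k = k, stride = as.integer(stride),
             expand = expand, skip = (stride == 1L && cin == cout))
  if (expand != 1L) {
    bl$expand_conv <- new_conv(1L, cin, ce)
    bl$bn0 <- new_bn(ce)
  }
  bl$dw <- new_dwconv(k, ce, stride)
  bl$bn1 <- new_bn(ce)
  bl$se <- new_se(ce, max(1L, round(cin * se_ratio)))
  bl$project <- new_conv(1L, ce, cout)
  bl$bn2 <- new_bn(cout)
  bl
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# Hidden width of a bespoke fusion gate: C/r, clamped below at 8 (or at C
# itself when the map is narrower than 8 channels).
gate_hidden_width <- function(C, r = 16L) {
  max(min(C, 8L), C %/% r)
}

#' Build the (optionally boosted) backbone
#'
#' Constructs the convolutional feature extractor plus classifier described
#' by a [model_config()]: a stem convolution, 26 MBConv blocks in seven
#' stages, a 1x1 head convolution, and a classifier head that is either the
#' plain pooled-features linear layer or, with `ff = TRUE`, a feature-fusion
#' head over the tapped block outputs (with optional squeeze-and-excitation
#' gates when `attention = TRUE`). With all flags off the model is the
#' standard backbone classifier. Weights are initialized from
#' `config$seed`, so construction is fully reproducible.
#'
#' @param config A [model_config()].
#' @return An opaque model object of class `"patchboost_model"`.
#' @export
build_backbone <- function(config) {
  if (!inherits(config, "patchboost_config")) {
    stop("config must come from model_config()")
  }
  sp <- backbone_spec(config$preset)
  nb <- sum(sp$depths)
  with_seed(config$seed, {
    stem <- list(conv = new_conv(3L, 3L, sp$stem, stride = 2L),
                 bn = new_bn(sp$stem))
    blocks <- list()
    couts <- integer(nb)
    cin <- sp$stem
    bi <- 0L
    for (s in seq_along(sp$depths)) {
      for (d in seq_len(sp$depths[s])) {
        bi <- bi + 1L
        stride <- if (d == 1L) sp$strides[s] else 1L
        blocks[[paste0("b", bi)]] <-
          new_mbconv(cin, sp$channels[s], sp$kernels[s], stride, sp$expand[s])
        couts[bi] <- sp$channels[s]
        cin <- sp$channels[s]
      }
    }
    head <- list(conv = new_conv(1L, cin, sp$head), bn = new_bn(sp$head))
    tap_channels <- couts[config$tap_indices]
    fused_len <- if (config$ff) sum(tap_channels) + sp$head else sp$head
    gates <- NULL
    if (config$attention) {
      gates <- list()
      if (config$ff) {
        for (i in seq_along(config$tap_indices)) {
          gates[[paste0("g", i)]] <- gate_params(tap_channels[i])
        }
      }
      gates$gfinal <- gate_params(sp$head)
    }
    fc <- new_dense(fused_len, config$num_classes, sd = sqrt(1 / fused_len))
    model <- list(config = config, spec = sp, stem = stem, blocks = blocks,
                  head = head, gates = gates, fc = fc,
                  block_channels = couts, fused_len = fused_len,
                  rds_applied = FALSE, norm_stats = NULL)
    if (config$rds) model <- reduce_downsampling(model)
    structure(model, class = "patchboost_model")
  })
}

#' Reduce the downsampling scale of a model
#'
#' Changes the stride of the first (stem) convolution from 2 to 1 so that
#' the overall downsampling factor becomes 16 instead of 32: every
#' intermediate and final feature map doubles its spatial side (a 96x96
#' input yields a 6x6 instead of a 3x3 final map). No parameter shapes
#' change. Applying it twice is an error.
#'
#' @param model A `"patchboost_model"`.
#' @return The modified model.
#' @export
reduce_downsampling <- function(model) {
  if (isTRUE(model$rds_applied)) {
    stop("reduce_downsampling() has already been applied to this model")
  }
  model$stem$conv$stride <- 1L
  model$rds_applied <- TRUE
  model$config$rds <- TRUE
  model
}

mbconv_fwd <- function(bl, x, training) {
  cc <- list()
  h <- x
  if (bl$expand != 1L) {
    r <- conv_fwd(bl$expand_conv, h); cc$expand <- r$cache; h <- r$y
    r <- bn_fwd(bl$bn0, h, training); cc$bn0 <- r$cache; bl$bn0 <- r$layer
    r2 <- swish_fwd(r$y); cc$sw0 <- r2$cache; h <- r2$y
  }
  r <- dwconv_fwd(bl$dw, h); cc$dw <- r$cache; h <- r$y
  r <- bn_fwd(bl$bn1, h, training); cc$bn1 <- r$cache; bl$bn1 <- r$layer
  r2 <- swish_fwd(r$y); cc$sw1 <- r2$cache; h <- r2$y
  r <- se_fwd(bl$se, h); cc$se <- r$cache; h <- r$y
  r <- conv_fwd(bl$project, h); cc$project <- r$cache; h <- r$y
  r <- bn_fwd(bl$bn2, h, training); cc$bn2 <- r$cache; bl$bn2 <- r$layer
  h <- r$y
  if (bl$skip) h <- h + x
  list(y = h, cache = cc, layer = bl)
}

mbconv_bwd <- function(bl, cc, dy) {
  g <- list()
  d <- dy
  r <- bn_bwd(bl$bn2, cc$bn2, d); g$bn2 <- r$g; d <- r$dx
  r <- conv_bwd(bl$project, cc$project, d); g$project <- r$g; d <- r$dx
  r <- se_bwd(bl$se, cc$se, d); g$se <- r$g; d <- r$dx
  d <- swish_bwd(cc$sw1, d)
  r <- bn_bwd(bl$bn1, cc$bn1, d); g$bn1 <- r$g; d <- r$dx
  r <- dwconv_bwd(bl$dw, cc$dw, d); g$dw <- r$g; d <- r$dx
  if (bl$expand != 1L) {
    d <- swish_bwd(cc$sw0, d)
    r <- bn_bwd(bl$bn0, cc$bn0, d); g$bn0 <- r$g; d <- r$dx
    r <- conv_bwd(bl$expand_conv, cc$expand, d); g$expand_conv <- r$g; d <- r$dx
  }
  if (bl$skip) d <- d + dy
  list(dx = d, g = g)
}

# Validate and convert a batch of images (H, W, 3[, N], values already
# normalized) to the internal (H, W, N, C) layout.
to_net_layout <- function(images, expected = 96L) {
  d <- dim(images)
  if (length(d) == 3L) {
    dim(images) <- c(d, 1L)
    d <- dim(images)
  }
  if (length(d) != 4L || d[3L] != 3L) {
    stop("expected images of shape (H, W, 3[, N]); got dim ",
         paste(d, collapse = "x"))
  }
  if (d[1L] != d[2L] || d[1L] < 32L) {
    stop("input resolution ", d[1L], "x", d[2L],
         " not supported: expected a square image of side >= 32 (e.g. ",
         expected, "x", expected, ")")
  }
  aperm(images, c(1L, 2L, 4L, 3L))
}

# Full forward pass in internal layout; returns logits, the tapped and
# final feature maps, and (when keep_cache) everything needed for backward.
fwd_net <- function(model, x, training = FALSE, keep_cache = FALSE) {
  taps <- model$config$tap_indices
  cc <- if (keep_cache) list(blocks = list()) else NULL
  r <- conv_fwd(model$stem$conv, x)
  if (keep_cache) cc$stem_conv <- r$cache
  r2 <- bn_fwd(model$stem$bn, r$y, training)
  model$stem$bn <- r2$layer
  if (keep_cache) cc$stem_bn <- r2$cache
  r3 <- swish_fwd(r2$y)
  if (keep_cache) cc$stem_sw <- r3$cache
  h <- r3$y
  tap_maps <- list()
  for (i in seq_along(model$blocks)) {
    nm <- paste0("b", i)
    rb <- mbconv_fwd(model$blocks[[nm]], h, training)
    model$blocks[[nm]] <- rb$layer
    if (keep_cache) cc$blocks[[nm]] <- rb$cache
    h <- rb$y
    if (i %in% taps) tap_maps[[nm]] <- h
  }
  r <- conv_fwd(model$head$conv, h)
  if (keep_cache) cc$head_conv <- r$cache
  r2 <- bn_fwd(model$head$bn, r$y, training)
  model$head$bn <- r2$layer
  if (keep_cache) cc$head_bn <- r2$cache
  r3 <- swish_fwd(r2$y)
  if (keep_cache) cc$head_sw <- r3$cache
  final <- r3$y

  # classifier head
  head_cc <- list()
  pooled <- list()
  if (model$config$ff) {
    maps <- c(tap_maps, list(gfinal = final))
    gate_names <- c(paste0("g", seq_along(taps)), "gfinal")
    for (j in seq_along(maps)) {
      m <- maps[[j]]
      if (model$config$attention) {
        gr <- gate_fwd(model$gates[[gate_names[j]]], m)
        if (keep_cache) head_cc[[paste0("gate_", gate_names[j])]] <- gr$cache
        m <- gr$y
      }
      pr <- gap_fwd(m)
      if (keep_cache) head_cc[[paste0("pool_", j)]] <- pr$cache
      pooled[[j]] <- pr$y
    }
    fused <- do.call(cbind, pooled)
  } else {
    m <- final
    if (model$config$attention) {
      gr <- gate_fwd(model$gates$gfinal, m)
      if (keep_cache) head_cc$gate_gfinal <- gr$cache
      m <- gr$y
    }
    pr <- gap_fwd(m)
    if (keep_cache) head_cc$pool_final <- pr$cache
    fused <- pr$y
  }
  rf <- dense_fwd(model$fc, fused)
  if (keep_cache) head_cc$fc <- rf$cache
  list(logits = rf$y, final = final, taps = tap_maps, fused = fused,
       cache = cc, head_cache = head_cc, model = model)
}

# Backward pass; fw is the result of fwd_net(..., keep_cache = TRUE).
bwd_net <- function(model, fw, dlogits) {
  taps <- model$config$tap_indices
  g <- list()
  r <- dense_bwd(model$fc, fw$head_cache$fc, dlogits)
  g$fc <- r$g
  dfused <- r$dx
  tap_grads <- list()
  if (model$config$ff) {
    gate_names <- c(paste0("g", seq_along(taps)), "gfinal")
    widths <- c(model$block_channels[taps], model$spec$head)
    off <- 0L
    g$gates <- list()
    for (j in seq_along(widths)) {
      dp <- dfused[, off + seq_len(widths[j]), drop = FALSE]
      off <- off + widths[j]
      dm <- gap_bwd(fw$head_cache[[paste0("pool_", j)]], dp)
      if (model$config$attention) {
        gr <- gate_bwd(model$gates[[gate_names[j]]],
                       fw$head_cache[[paste0("gate_", gate_names[j])]], dm)
        g$gates[[gate_names[j]]] <- gr$g
        dm <- gr$dx
      }
      if (j <= length(taps)) {
        tap_grads[[paste0("b", taps[j])]] <- dm
      } else {
        dfinal <- dm
      }
    }
    if (!model$config$attention) g$gates <- NULL
  } else {
    dm <- gap_bwd(fw$head_cache$pool_final, dfused)
    if (model$config$attention) {
      gr <- gate_bwd(model$gates$gfinal, fw$head_cache$gate_gfinal, dm)
      g$gates <- list(gfinal = gr$g)
      dm <- gr$dx
    }
    dfinal <- dm
  }
  d <- swish_bwd(fw$cache$head_sw, dfinal)
  r <- bn_bwd(model$head$bn, fw$cache$head_bn, d)
  g$head <- list(bn = r$g)
  r2 <- conv_bwd(model$head$conv, fw$cache$head_conv, r$dx)
  g$head$conv <- r2$g
  d <- r2$dx
  g$blocks <- list()
  for (i in rev(seq_along(model$blocks))) {
    nm <- paste0("b", i)
    if (!is.null(tap_grads[[nm]])) d <- d + tap_grads[[nm]]
    rb <- mbconv_bwd(model$blocks[[nm]], fw$cache$blocks[[nm]], d)
    g$blocks[[nm]] <- rb$g
    d <- rb$dx
  }
  d <- swish_bwd(fw$cache$stem_sw, d)
  r <- bn_bwd(model$stem$bn, fw$cache$stem_bn, d)
  g$stem <- list(bn = r$g)
  r2 <- conv_bwd(model$stem$conv, fw$cache$stem_conv, r$dx)
  g$stem$conv <- r2$g
  g
}

#' Forward pass: per-class scores for a batch of images
#'
#' Runs the model in evaluation mode (batch norm uses running statistics,
#' no augmentation) and returns one row of scores per image. Images must be
#' square, 3-channel, already normalized; a wrong resolution is rejected
#' with the expected and actual sizes.
#'
#' @param model A `"patchboost_model"`.
#' @param images Array `(H, W, 3)` or `(H, W, 3, N)`.
#' @param type `"prob"` for softmax probabilities, `"logit"` for raw scores.
#' @return An `N x num_classes` matrix; column 2 is the positive class.
#' @export
forward <- function(model, images, type = c("prob", "logit")) {
  type <- match.arg(type)
  x <- to_net_layout(images)
  out <- fwd_net(model, x, training = FALSE)
  if (type == "prob") softmax_rows(out$logits) else out$logits
}

#' Feature maps of a forward pass
#'
#' Like [forward()] but returns the tapped block outputs, the final feature
#' map (after the head convolution), and the fused feature vector, for
#' inspection of the architecture (spatial sides, channel counts, fusion
#' length).
#'
#' @inheritParams forward
#' @return A list with `logits`, `taps` (named list of `(H, W, N, C)`
#'   arrays), `final`, and `fused`.
#' @export
forward_features <- function(model, images) {
  x <- to_net_layout(images)
  out <- fwd_net(model, x, training = FALSE)
  out[c("logits", "taps", "final", "fused")]
}

# Straight-line reference path: stem -> blocks -> head -> pool -> linear.
# Deliberately ignores taps, gates and fusion; with all flags off it must
# produce scores identical to forward().
forward_plain <- function(model, images, type = c("prob", "logit")) {
  type <- match.arg(type)
  x <- to_net_layout(images)
  h <- swish_fwd(bn_fwd(model$stem$bn, conv_fwd(model$stem$conv, x)$y,
                        FALSE)$y)$y
  for (nm in names(model$blocks)) {
    h <- mbconv_fwd(model$blocks[[nm]], h, FALSE)$y
  }
  h <- swish_fwd(bn_fwd(model$head$bn, conv_fwd(model$head$conv, h)$y,
                        FALSE)$y)$y
  logits <- dense_fwd(model$fc, gap_fwd(h)$y)$y
  if (type == "prob") softmax_rows(logits) else logits
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: the configuration (and normalization
#' statistics, when the model has been trained) are stored alongside the
#' weights, so a loaded checkpoint can be evaluated directly.
#'
#' @param model A `"patchboost_model"`.
#' @param path File path.
#' @return `checkpoint_load()` returns the model.
#' @export
checkpoint_save <- function(model, path) {
  saveRDS(list(format = 1L, package = "patchboost", model = model), path)
  invisible(path)
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, 1L) ||
      !inherits(x$model, "patchboost_model")) {
    stop("not a patchboost checkpoint: ", path)
  }
  x$model
}
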