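#' Training configuration
#'
#' Defaults follow the training protocol used for the boosted backbone on
#' the patch data: 30 epochs of Adam at an initial learning rate of 0.003,
#' decayed by a factor of 10 at the 15th and 23rd epochs (inclusive),
#' batch size 256, a stratified 0.9/0.1 train/validation split, random
#' horizontal and vertical flips and per-channel normalization at train
#' time. Test-scale runs shrink `epochs`, `batch_size` and the dataset,
#' not the learning-rate schedule.
#'
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param base_lr Initial learning rate.
#' @param decay_epochs Strictly increasing epochs (within `[1, epochs]`)
#'   at which the rate is divided by `decay_factor`, boundary inclusive.
#' @param decay_factor Decay divisor.
#' @param split_ratio Train fraction of a [split_dataset()] call, in (0,1).
#' @param seed Seed of a single [train()] run.
#' @param seeds Seed vector for multi-run aggregation ([run_ablation()]).
#' @param crop_mode `NULL` (follow the model's `rcc` flag), `"rcc"`,
#'   `"none"`, or `"destructive"` (the center-destructive control crop).
#' @param early_stop_acc Optional validation accuracy at which training
#'   stops before `epochs` is exhausted (checked after each epoch).
#' @param verbose Print one structured log line per epoch.
#' @return A list of class `"patchboost_train_config"`.
#' @export
train_config <- function(epochs = 30L, batch_size = 256L, base_lr = 0.003,
                         decay_epochs = c(15L, 23L), decay_factor = 10,
                         split_ratio = 0.9, seed = 1L, seeds = c(1L, 2L, 3L),
                         crop_mode = NULL, early_stop_acc = NULL,
                         verbose = FALSE) {
  epochs <- as.integer(epochs)
  decay_epochs <- as.integer(decay_epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (length(decay_epochs)) {
    if (any(diff(decay_epochs) <= 0L)) {
      stop("decay_epochs must be strictly increasing")
    }
    if (any(decay_epochs < 1L) || any(decay_epochs > epochs)) {
      stop("decay_epochs must lie within [1, epochs]")
    }
  }
  if (split_ratio <= 0 || split_ratio >= 1) {
    stop("split_ratio must lie strictly in (0, 1)")
  }
  if (!is.null(crop_mode)) {
    crop_mode <- match.arg(crop_mode, c("rcc", "none", "destructive"))
  }
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 base_lr = base_lr, decay_epochs = decay_epochs,
                 decay_factor = decay_factor, split_ratio = split_ratio,
                 seed = as.integer(seed), seeds = as.integer(seeds),
                 crop_mode = crop_mode, early_stop_acc = early_stop_acc,
                 verbose = isTRUE(verbose)),
            class = "patchboost_train_config")
}

#' Learning rate at a given epoch
#'
#' Piecewise-constant step schedule:
#' `base_lr / decay_factor^(number of decay epochs <= epoch)`. Decay
#' epochs are boundary inclusive, so with the defaults epochs 1-14 run at
#' 0.003, epochs 15-22 at 0.0003 and epochs 23-30 at 0.00003.
#'
#' @param epoch Integer in `[1, cfg$epochs]`.
#' @param cfg A [train_config()].
#' @return The learning rate (non-increasing in `epoch`).
#' @export
lr_at <- function(epoch, cfg) {
  epoch <- as.integer(epoch)
  if (is.na(epoch) || epoch < 1L || epoch > cfg$epochs) {
    stop("epoch must lie in [1, ", cfg$epochs, "]")
  }
  cfg$base_lr / cfg$decay_factor^sum(cfg$decay_epochs <= epoch)
}

#' Stratified train/validation split
#'
#' Splits a dataset (or a manifest data.frame with a `label` column) into
#' disjoint, exhaustive train and validation parts, preserving the class
#' proportions to within one sample per class, deterministically for a
#' given seed.
#'
#' @param ds A `"patch_dataset"` or a data.frame with a `label` column.
#' @param ratio Train fraction, strictly in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `val` of the input's type.
#' @export
split_dataset <- function(ds, ratio = 0.9, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly in (0, 1)")
  labels <- if (inherits(ds, "patch_dataset")) ds$labels else ds$label
  if (is.null(labels)) stop("ds must have labels")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  set.seed(seed)
  tr_idx <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    take <- round(ratio * length(idx))
    tr_idx <- c(tr_idx, sample(idx, take))
  }
  tr_idx <- sort(tr_idx)
  va_idx <- setdiff(seq_along(labels), tr_idx)
  list(train = subset_dataset(ds, tr_idx), val = subset_dataset(ds, va_idx))
}

subset_dataset <- function(ds, idx) {
  if (inherits(ds, "patch_dataset")) {
    new_patch_dataset(ds$images[, , , idx, drop = FALSE], ds$labels[idx],
                      ds$ids[idx])
  } else {
    ds[idx, , drop = FALSE]
  }
}

# Train-time augmentation of one (96, 96, 3, nb) image block, in place.
augment_batch <- function(imgs, crop_mode) {
  nb <- dim(imgs)[4L]
  for (i in seq_len(nb)) {
    im <- imgs[, , , i]
    if (crop_mode == "rcc") {
      im <- random_center_crop(im)
    } else if (crop_mode == "destructive") {
      im <- destructive_crop(im)
    }
    imgs[, , , i] <- random_flip(im)
  }
  imgs
}

#' Train a model
#'
#' Full training driver: builds the backbone from `model_cfg` (seeded by
#' `train_cfg$seed`), computes per-channel normalization statistics on the
#' training split only, and runs mini-batch Adam under the step
#' learning-rate schedule. Train-time augmentation is random center
#' cropping (iff the `rcc` flag is on, or as overridden by
#' `train_cfg$crop_mode`) followed by random flips; normalization is
#' always applied. The evaluation path applies no cropping or flipping.
#' The checkpoint with the best validation accuracy is retained alongside
#' the final-epoch model. Runs are fully reproducible on a single device
#' for a fixed `(seed, config, data)`.
#'
#' @param train_ds,val_ds `"patch_dataset"` objects (see
#'   [split_dataset()]); both must be non-empty.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @return A list of class `"patchboost_fit"` with `model` (best
#'   validation accuracy), `final_model` (last epoch), and `history`
#'   (data.frame with epoch, lr, train loss and validation metrics).
#' @export
train <- function(train_ds, val_ds, model_cfg, train_cfg = train_config()) {
  if (!inherits(train_ds, "patch_dataset") ||
      !inherits(val_ds, "patch_dataset")) {
    stop("train_ds and val_ds must be patch_dataset objects")
  }
  if (length(train_ds$labels) == 0L || length(val_ds$labels) == 0L) {
    stop("empty train or validation split")
  }
  crop_mode <- train_cfg$crop_mode
  if (is.null(crop_mode)) crop_mode <- if (model_cfg$rcc) "rcc" else "none"
  model_cfg$seed <- train_cfg$seed
  model <- build_backbone(model_cfg)
  stats <- compute_norm_stats(train_ds)
  model$norm_stats <- stats
  set.seed(train_cfg$seed)
  n <- length(train_ds$labels)
  y <- train_ds$labels + 1L  # 1-based class index
  adam <- list(m = NULL, v = NULL, t = 0L)
  history <- NULL
  best <- list(acc = -Inf, model = NULL)
  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- lr_at(epoch, train_cfg)
    ord <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = train_cfg$batch_size)) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1L, n)]
      imgs <- train_ds$images[, , , idx, drop = FALSE]
      imgs <- augment_batch(imgs, crop_mode)
      imgs <- normalize_images(imgs, stats)
      x <- aperm(imgs, c(1L, 2L, 4L, 3L))
      fw <- fwd_net(model, x, training = TRUE, keep_cache = TRUE)
      model <- fw$model  # running BN statistics
      ce <- softmax_ce(fw$logits, y[idx])
      losses <- c(losses, ce$loss)
      g <- bwd_net(model, fw, ce$dlogits)
      if (is.null(adam$m)) {
        adam$m <- tree_zero(g)
        adam$v <- tree_zero(g)
      }
      adam$t <- adam$t + 1L
      up <- adam_tree(model, g, adam$m, adam$v, lr, 0.9, 0.999, 1e-8, adam$t)
      model <- up$p
      adam$m <- up$m
      adam$v <- up$v
    }
    val_rep <- evaluate(model, val_ds)
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                loss = mean(losses),
                                val_ACC = val_rep$ACC, val_AUC = val_rep$AUC))
    if (train_cfg$verbose) {
      message(sprintf("epoch %d lr %.2g loss %.4f val_ACC %.4f val_AUC %s",
                      epoch, lr, mean(losses), val_rep$ACC,
                      ifelse(is.na(val_rep$AUC), "NA",
                             sprintf("%.4f", val_rep$AUC))))
    }
    if (!is.na(val_rep$ACC) && val_rep$ACC > best$acc) {
      best <- list(acc = val_rep$ACC, model = model)
    }
    if (!is.null(train_cfg$early_stop_acc) &&
        !is.na(val_rep$ACC) && val_rep$ACC >= train_cfg$early_stop_acc) {
      break
    }
  }
  structure(list(model = best$model, final_model = model, history = history),
            class = "patchboost_fit")
}

#' Evaluate a model on a dataset
#'
#' Forward passes in evaluation mode (no augmentation; batch norm uses
#' running statistics; normalization uses the statistics stored in the
#' model at training time) and the five-indicator metrics report.
#'
#' @param model A trained `"patchboost_model"` (or a `"patchboost_fit"`,
#'   whose best model is used).
#' @param ds A `"patch_dataset"`.
#' @param batch_size Evaluation batch size.
#' @return A `"patchboost_metrics"` report.
#' @export
evaluate <- function(model, ds, batch_size = 128L) {
  if (inherits(model, "patchboost_fit")) model <- model$model
  if (is.null(model$norm_stats)) {
    stop("model has no normalization statistics; train it first")
  }
  scores <- predict_scores(model, ds, batch_size)
  metrics_report(scores, ds$labels)
}

# Positive-class probabilities for every patch in ds.
predict_scores <- function(model, ds, batch_size = 128L) {
  n <- length(ds$labels)
  scores <- numeric(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    imgs <- normalize_images(ds$images[, , , idx, drop = FALSE],
                             model$norm_stats)
    p <- forward(model, imgs, type = "prob")
    scores[idx] <- p[, 2L]
  }
  scores
}

#' All 16 strategy combinations
#'
#' @return A data.frame with logical columns `rcc`, `rds`, `ff`,
#'   `attention`, one row per combination, baseline first.
#' @export
ablation_grid <- function() {
  g <- expand.grid(attention = c(FALSE, TRUE), ff = c(FALSE, TRUE),
                   rds = c(FALSE, TRUE), rcc = c(FALSE, TRUE))
  g[, c("rcc", "rds", "ff", "attention")]
}

#' Run an ablation over strategy combinations
#'
#' Trains and evaluates every flag combination in `grid` over the same
#' seed list (`train_cfg$seeds`) and the same train/validation split, and
#' aggregates validation ACC and AUC (mean, and across-seed sd when more
#' than one seed) into one row per combination, in the conventional
#' ablation-table layout (RCC, RDS, FF, Attention, ACC, AUC). Duplicate
#' combinations are collapsed with a warning.
#'
#' @param grid A data.frame like [ablation_grid()] (or a list of named
#'   flag lists).
#' @param train_ds,val_ds Datasets, see [train()].
#' @param model_cfg Base [model_config()]; its flags are overridden per
#'   row.
#' @param train_cfg A [train_config()]; `seeds` drives the repeats.
#' @return A data.frame of class `"patchboost_ablation"` with columns
#'   `RCC`, `RDS`, `FF`, `Attention`, `ACC`, `AUC` (percent) and, with
#'   two or more seeds, `ACC_sd`, `AUC_sd`.
#' @export
run_ablation <- function(grid, train_ds, val_ds,
                         model_cfg = model_config("tiny"),
                         train_cfg = train_config()) {
  if (is.list(grid) && !is.data.frame(grid)) {
    grid <- do.call(rbind, lapply(grid, as.data.frame))
  }
  if (nrow(grid) == 0L) stop("grid must be non-empty")
  for (f in c("rcc", "rds", "ff", "attention")) {
    if (is.null(grid[[f]])) stop("grid lacks flag column '", f, "'")
  }
  key <- do.call(paste, grid[, c("rcc", "rds", "ff", "attention")])
  if (anyDuplicated(key)) {
    warning("duplicate flag combinations collapsed")
    grid <- grid[!duplicated(key), , drop = FALSE]
  }
  rows <- NULL
  for (i in seq_len(nrow(grid))) {
    cfg_i <- model_cfg
    cfg_i$rcc <- isTRUE(grid$rcc[i])
    cfg_i$rds <- isTRUE(grid$rds[i])
    cfg_i$ff <- isTRUE(grid$ff[i])
    cfg_i$attention <- isTRUE(grid$attention[i])
    reps <- lapply(train_cfg$seeds, function(s) {
      tc <- train_cfg
      tc$seed <- s
      fit <- train(train_ds, val_ds, cfg_i, tc)
      evaluate(fit$model, val_ds)
    })
    acc <- vapply(reps, `[[`, numeric(1), "ACC")
    auc <- vapply(reps, `[[`, numeric(1), "AUC")
    row <- data.frame(RCC = cfg_i$rcc, RDS = cfg_i$rds, FF = cfg_i$ff,
                      Attention = cfg_i$attention,
                      ACC = 100 * mean(acc), AUC = 100 * mean(auc))
    if (length(train_cfg$seeds) >= 2L) {
      row$ACC_sd <- 100 * stats::sd(acc)
      row$AUC_sd <- 100 * stats::sd(auc)
    }
    rows <- rbind(rows, row)
  }
  class(rows) <- c("patchboost_ablation", "data.frame")
  rows
}

#' Write an ablation table as CSV
#'
#' @param rows A [run_ablation()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ablation_csv <- function(rows, path) {
  out <- rows
  for (f in c("ACC", "AUC", "ACC_sd", "AUC_sd")) {
    if (!is.null(out[[f]])) out[[f]] <- sprintf("%.2f", out[[f]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
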