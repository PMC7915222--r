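#' Parameters for the synthetic patch generator
#'
#' The generator emulates the structure of the PCam-style lymph-node patch
#' data: 96x96 RGB patches, binary labels with an unbalanced positive
#' fraction (default 130908/220025, the positive:negative ratio of the
#' original manifest), and a discriminative signal confined to the central
#' 32x32 window. Negative patches are a stationary pink-tinted random
#' field (smooth low-resolution texture plus fine pixel noise), identical
#' in distribution everywhere; positive patches additionally receive
#' nuclei-like dark elliptical blobs strictly inside the central window.
#'
#' @param n Number of patches (>= 2 for [make_dataset()]).
#' @param pos_fraction Target fraction of positive labels, in (0, 1).
#' @param seed Integer seed; identical parameters give bit-identical output.
#' @param signal_strength Amplitude (in intensity units, image range
#'   `[0, 1]`) of the center blobs; 0 makes classes indistinguishable.
#' @param blob_count Number of elliptical blobs per positive patch.
#' @param field_res Side of the coarse texture grid that is bilinearly
#'   upsampled to 96x96 (controls the texture correlation length).
#' @param field_amp Standard deviation of the coarse texture field.
#' @param noise_sd Standard deviation of the fine per-pixel noise.
#' @return A list of class `"patchboost_gen"`.
#' @export
gen_params <- function(n, pos_fraction = 130908 / 220025, seed = 1L,
                       signal_strength = 0.4, blob_count = 9L,
                       field_res = 12L, field_amp = 0.07, noise_sd = 0.04) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (!is.numeric(pos_fraction) || pos_fraction <= 0 || pos_fraction >= 1) {
    stop("pos_fraction must lie strictly in (0, 1)")
  }
  if (signal_strength < 0) stop("signal_strength must be >= 0")
  structure(list(n = n, pos_fraction = pos_fraction, seed = as.integer(seed),
                 signal_strength = signal_strength,
                 blob_count = as.integer(blob_count),
                 field_res = as.integer(field_res),
                 field_amp = field_amp, noise_sd = noise_sd,
                 side = 96L, center = 32L),
            class = "patchboost_gen")
}

# Interpolation matrix for bilinear resampling of a length-n_in axis to
# n_out samples (pixel-center alignment).
bilinear_weights <- function(n_in, n_out) {
  P <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  i0 <- pmin(pmax(floor(src), 1L), n_in)
  i1 <- pmin(i0 + 1L, n_in)
  w <- pmin(pmax(src - i0, 0), 1)
  P[cbind(seq_len(n_out), i0)] <- P[cbind(seq_len(n_out), i0)] + (1 - w)
  P[cbind(seq_len(n_out), i1)] <- P[cbind(seq_len(n_out), i1)] + w
  P
}

# Index range (1-based) of the central window.
center_idx <- function(side = 96L, center = 32L) {
  off <- (side - center) %/% 2L
  (off + 1L):(off + center)
}

#' Generate one labeled patch
#'
#' Draws a single 96x96x3 patch from the generator's background process
#' and, iff `label == 1`, superimposes dark elliptical blobs of amplitude
#' `signal_strength` strictly inside the central 32x32 window. Values are
#' clipped to `[0, 1]`. The patch is drawn from the current RNG stream
#' unless `seed` is given, in which case the stream is seeded first (so the
#' same `(label, seed)` always yields the identical image).
#'
#' @param label 0 or 1.
#' @param params A [gen_params()] object.
#' @param seed Optional integer seed.
#' @return Numeric array `(96, 96, 3)` in `[0, 1]`.
#' @export
make_patch <- function(label, params, seed = NULL) {
  if (length(label) != 1L || !(label %in% c(0, 1))) {
    stop("label must be a single value in {0, 1}; got ",
         paste(label, collapse = ","))
  }
  if (!is.null(seed)) set.seed(seed)
  s <- params$side
  fr <- params$field_res
  Pr <- bilinear_weights(fr, s)
  tint <- c(0.80, 0.62, 0.78)  # eosin-pink base tone
  img <- array(0, dim = c(s, s, 3L))
  shared <- Pr %*% matrix(stats::rnorm(fr * fr, sd = params$field_amp),
                          fr, fr) %*% t(Pr)
  for (ch in 1:3) {
    own <- Pr %*% matrix(stats::rnorm(fr * fr, sd = params$field_amp / 2),
                         fr, fr) %*% t(Pr)
    img[, , ch] <- tint[ch] + shared + own +
      stats::rnorm(s * s, sd = params$noise_sd)
  }
  if (label == 1 && params$signal_strength > 0 && params$blob_count > 0L) {
    cw <- params$center
    mask <- matrix(0, cw, cw)
    ii <- matrix(seq_len(cw), cw, cw)
    jj <- t(ii)
    for (b in seq_len(params$blob_count)) {
      a1 <- stats::runif(1, 3, 6)
      a2 <- stats::runif(1, 3, 6)
      ci <- stats::runif(1, 1 + a1, cw - a1)
      cj <- stats::runif(1, 1 + a2, cw - a2)
      th <- stats::runif(1, 0, pi)
      di <- (ii - ci) * cos(th) + (jj - cj) * sin(th)
      dj <- -(ii - ci) * sin(th) + (jj - cj) * cos(th)
      mask <- mask + exp(-2 * ((di / a1)^2 + (dj / a2)^2))
    }
    mask <- pmin(mask, 1)
    chw <- c(0.9, 1.0, 0.7)  # basophilic: darkens green/red more than blue
    ci_rows <- center_idx(s, cw)
    for (ch in 1:3) {
      img[ci_rows, ci_rows, ch] <- img[ci_rows, ci_rows, ch] -
        params$signal_strength * chw[ch] * mask
    }
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# Deterministic label vector: round(n * pos_fraction) positives placed by a
# seeded permutation (counts are exact, not Bernoulli draws).
assign_labels <- function(params) {
  npos <- as.integer(round(params$n * params$pos_fraction))
  labels <- integer(params$n)
  labels[sample.int(params$n, npos)] <- 1L
  labels
}

#' Generate an in-memory synthetic dataset
#'
#' Like [make_dataset()] but keeps the patches in memory instead of writing
#' PNG files; both functions draw from the same seeded stream, so patch i
#' is identical across the two (up to the 8-bit PNG quantization of the
#' on-disk copy).
#'
#' @param params A [gen_params()] object.
#' @return A list of class `"patch_dataset"` with `images`
#'   (`(96, 96, 3, n)` array), `labels`, `ids` and `pos_fraction`.
#' @export
synthesize_patches <- function(params) {
  set.seed(params$seed)
  labels <- assign_labels(params)
  images <- array(0, dim = c(params$side, params$side, 3L, params$n))
  for (i in seq_len(params$n)) {
    images[, , , i] <- make_patch(labels[i], params)
  }
  new_patch_dataset(images, labels, sprintf("syn_%06d", seq_len(params$n)))
}

new_patch_dataset <- function(images, labels, ids) {
  structure(list(images = images, labels = as.integer(labels), ids = ids,
                 pos_fraction = mean(labels == 1L)),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat("<patch_dataset> ", length(x$labels), " patches (",
      sum(x$labels == 1L), " positive, ", sum(x$labels == 0L),
      " negative), ", paste(dim(x$images)[1:3], collapse = "x"), "\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Generates `params$n` patches, writes them as 8-bit PNG files plus a
#' `labels.csv` manifest (header `id,label`) into `out_dir`, and returns
#' the manifest. Label counts are deterministic
#' (`round(n * pos_fraction)` positives) and the row order is a seeded
#' permutation, so the same parameters always produce a byte-identical
#' manifest and image set.
#'
#' @param params A [gen_params()] object with `n >= 2`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a `data.frame` manifest with columns `id`, `label`,
#'   `path` and attribute `pos_fraction`.
#' @export
make_dataset <- function(params, out_dir) {
  if (params$n < 2L) stop("make_dataset() needs n >= 2")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  set.seed(params$seed)
  labels <- assign_labels(params)
  ids <- sprintf("syn_%06d", seq_len(params$n))
  paths <- paste0(ids, ".png")
  for (i in seq_len(params$n)) {
    png::writePNG(make_patch(labels[i], params),
                  file.path(out_dir, paths[i]))
  }
  manifest <- data.frame(id = ids, label = labels, path = paths,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest[, c("id", "label")],
                   file.path(out_dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  attr(manifest, "pos_fraction") <- mean(labels == 1L)
  invisible(manifest)
}

#' Load a patch dataset from a directory
#'
#' Reads `labels.csv` (columns `id,label`; an optional `path` column gives
#' image locations, otherwise `<id>.png` is assumed) and the referenced
#' PNG files.
#'
#' @param dir Directory written by [make_dataset()] (or laid out the same
#'   way).
#' @return A `"patch_dataset"` object.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "labels.csv")
  if (!file.exists(mf)) stop("no labels.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  paths <- if ("path" %in% names(manifest)) manifest$path
           else paste0(manifest$id, ".png")
  first <- png::readPNG(file.path(dir, paths[1L]))
  images <- array(0, dim = c(dim(first), nrow(manifest)))
  images[, , , 1L] <- first
  for (i in seq_len(nrow(manifest))[-1L]) {
    images[, , , i] <- png::readPNG(file.path(dir, paths[i]))
  }
  new_patch_dataset(images, manifest$label, manifest$id)
}

#' Probe where the class signal lives
#'
#' Fits a one-dimensional threshold classifier on the mean intensity of
#' the central 32x32 window (respectively, of the periphery only) using
#' half of the patches, and reports the held-out accuracy of each. For a
#' generator that confines the class signal to the center, the center
#' probe should be highly accurate and the periphery probe near chance.
#'
#' @param ds A `"patch_dataset"` (>= 200 patches, both classes present) or
#'   a directory path for [load_dataset()]. The probe's train/test split is
#'   deterministic and stratified (alternating samples within each class),
#'   so it never interacts with the generator's RNG stream.
#' @return Named numeric vector `c(acc_center, acc_periphery)`.
#' @export
center_signal_probe <- function(ds) {
  if (is.character(ds)) ds <- load_dataset(ds)
  n <- length(ds$labels)
  if (n < 200L) stop("center_signal_probe() needs at least 200 patches")
  if (length(unique(ds$labels)) < 2L) {
    stop("center_signal_probe() needs both classes present")
  }
  side <- dim(ds$images)[1L]
  ci <- center_idx(side)
  f_center <- f_periph <- numeric(n)
  for (i in seq_len(n)) {
    img <- ds$images[, , , i]
    cen <- img[ci, ci, ]
    f_center[i] <- mean(cen)
    f_periph[i] <- (sum(img) - sum(cen)) / (length(img) - length(cen))
  }
  idx_pos <- which(ds$labels == 1L)
  idx_neg <- which(ds$labels == 0L)
  tr <- c(idx_pos[seq_along(idx_pos) %% 2L == 1L],
          idx_neg[seq_along(idx_neg) %% 2L == 1L])
  c(acc_center = threshold_probe_acc(f_center, ds$labels, tr),
    acc_periphery = threshold_probe_acc(f_periph, ds$labels, tr))
}

# Midpoint-of-class-means threshold fit on `tr`, held-out accuracy on the
# complement.
threshold_probe_acc <- function(f, labels, tr) {
  m1 <- mean(f[tr][labels[tr] == 1L])
  m0 <- mean(f[tr][labels[tr] == 0L])
  thr <- (m1 + m0) / 2
  te <- setdiff(seq_along(f), tr)
  pred <- if (m1 < m0) as.integer(f[te] < thr) else as.integer(f[te] > thr)
  mean(pred == labels[te])
}
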