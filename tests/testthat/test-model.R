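# Architectural checks run on the "tiny" preset (identical topology,
# strides and tap indices to the full-size backbone) with 64x64 inputs so
# the spatial arithmetic is exact; full-size facts are covered in the
# acceptance suite.

norm_input <- function(side, n = 1L, seed = 51L) {
  set.seed(seed)
  array(stats::rnorm(side * side * 3 * n), dim = c(side, side, 3, n))
}

test_that("configuration validates tap indices and flags", {
  expect_error(model_config("tiny", tap_indices = c(4, 4)), "increasing")
  expect_error(model_config("tiny", tap_indices = c(4, 30)), "\\[1, 26\\]")
  cfg <- model_config("tiny", ff = TRUE)
  expect_s3_class(cfg, "patchboost_config")
  expect_equal(cfg$tap_indices, c(4L, 7L, 17L, 25L))
})

test_that("construction is reproducible and exposes 26 blocks", {
  m1 <- build_backbone(model_config("tiny", seed = 5))
  m2 <- build_backbone(model_config("tiny", seed = 5))
  expect_identical(m1$blocks$b13$dw$W, m2$blocks$b13$dw$W)
  expect_identical(m1$fc$W, m2$fc$W)
  expect_length(m1$blocks, 26)
  m3 <- build_backbone(model_config("tiny", seed = 6))
  expect_false(identical(m1$fc$W, m3$fc$W))
})

test_that("forward returns one score row per image with the right shape", {
  m <- build_backbone(model_config("tiny", seed = 1))
  x <- norm_input(64, n = 4)
  p <- forward(m, x)
  expect_equal(dim(p), c(4, 2))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-12)
  expect_identical(p, forward(m, x))  # deterministic in eval mode
  expect_error(forward(m, norm_input(64)[1:60, , , ]), "64")
  expect_error(forward(m, array(0, c(16, 16, 3))), "32")
})

test_that("block outputs are observable at the tap indices", {
  m <- build_backbone(model_config("tiny", seed = 1))
  ft <- forward_features(m, norm_input(64))
  expect_named(ft$taps, c("b4", "b7", "b17", "b25"))
  # channel widths follow the stage table
  expect_equal(vapply(ft$taps, function(t) dim(t)[4], 1),
               c(b4 = 6, b7 = 12, b17 = 16, b25 = 24))
  # spatial sides follow the stride pattern: 64 -> 32, 16, 8, 4, 4, 2, 2
  expect_equal(vapply(ft$taps, function(t) dim(t)[1], 1),
               c(b4 = 16, b7 = 8, b17 = 4, b25 = 2))
  expect_equal(dim(ft$final)[1:2], c(2, 2))
})

test_that("reduced downsampling doubles every feature map side", {
  base <- build_backbone(model_config("tiny", seed = 2))
  rds <- reduce_downsampling(build_backbone(model_config("tiny", seed = 2)))
  x <- norm_input(64)
  fb <- forward_features(base, x)
  fr <- forward_features(rds, x)
  for (nm in names(fb$taps)) {
    expect_equal(dim(fr$taps[[nm]])[1:2], 2 * dim(fb$taps[[nm]])[1:2])
    expect_equal(dim(fr$taps[[nm]])[4], dim(fb$taps[[nm]])[4])
  }
  expect_equal(dim(fr$final)[1:2], 2 * dim(fb$final)[1:2])
  # parameter shapes unchanged; double application rejected
  expect_equal(dim(rds$stem$conv$W), dim(base$stem$conv$W))
  expect_error(reduce_downsampling(rds), "already")
})

test_that("the fused vector length is the sum of tap and head channels", {
  m <- build_backbone(model_config("tiny", ff = TRUE, seed = 3))
  expect_equal(m$fused_len, 6 + 12 + 16 + 24 + 48)
  ft <- forward_features(m, norm_input(64))
  expect_equal(ncol(ft$fused), m$fused_len)
  # independent of spatial input size
  ft96 <- forward_features(m, norm_input(96))
  expect_equal(ncol(ft96$fused), m$fused_len)
})

test_that("with all flags off the boosted path equals the plain backbone", {
  m <- build_backbone(model_config("tiny", seed = 4))
  x <- norm_input(64, n = 3)
  expect_identical(forward(m, x, type = "logit"),
                   patchboost:::forward_plain(m, x, type = "logit"))
  # an enabled attention gate changes the computation (the plain path
  # ignores it, so the two diverge)
  mf <- build_backbone(model_config("tiny", attention = TRUE, seed = 4))
  expect_false(isTRUE(all.equal(forward(mf, x, type = "logit"),
                                patchboost:::forward_plain(mf, x, type = "logit"))))
})

test_that("checkpoints round-trip through disk", {
  m <- build_backbone(model_config("tiny", ff = TRUE, seed = 8))
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  checkpoint_save(m, path)
  m2 <- checkpoint_load(path)
  x <- norm_input(64, n = 2)
  expect_identical(forward(m, x), forward(m2, x))
  expect_identical(m2$config$ff, TRUE)
  bad <- tempfile(fileext = ".rds")
  on.exit(unlink(bad), add = TRUE)
  saveRDS(list(1, 2), bad)
  expect_error(checkpoint_load(bad), "checkpoint")
})
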