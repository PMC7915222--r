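test_that("patch generation is seeded and validates its label", {
  p <- gen_params(n = 10, seed = 3)
  a <- make_patch(1, p, seed = 7)
  b <- make_patch(1, p, seed = 7)
  expect_identical(a, b)
  expect_equal(dim(a), c(96, 96, 3))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(make_patch(2, p), "label")
  expect_error(make_patch(c(0, 1), p), "label")
  expect_error(gen_params(n = 10, pos_fraction = 1.2), "pos_fraction")
})

test_that("negative patches are stationary: center matches periphery", {
  p <- gen_params(n = 1, seed = 5)
  set.seed(5)
  n <- 300
  f_center <- f_off <- numeric(n)
  for (i in seq_len(n)) {
    img <- make_patch(0, p)
    f_center[i] <- mean(img[33:64, 33:64, ])
    f_off[i] <- mean(img[9:40, 49:80, ])  # interior off-center window
  }
  # distribution equality of regional means on negatives
  ks <- suppressWarnings(ks.test(f_center, f_off))
  expect_gt(ks$p.value, 1e-3)
  expect_lt(abs(mean(f_center) - mean(f_off)), 0.02)
})

test_that("the class signal is confined to the central window", {
  p <- gen_params(n = 1, seed = 6)
  set.seed(6)
  pos <- make_patch(1, p)
  neg_region <- function(img) img[-(33:64), , ]
  # positives and negatives share the periphery process: amplitudes match
  set.seed(6)
  pos2 <- make_patch(1, p)
  set.seed(6)
  neg2 <- make_patch(0, p)
  expect_identical(neg_region(pos2), neg_region(neg2))
  # and the center of a positive is darker (blobs subtract intensity)
  expect_lt(mean(pos[33:64, 33:64, ]), mean(neg_region(pos)))
})

test_that("zero signal strength makes classes indistinguishable", {
  p0 <- gen_params(n = 1, seed = 7, signal_strength = 0)
  set.seed(7)
  a <- make_patch(1, p0)
  set.seed(7)
  b <- make_patch(0, p0)
  expect_identical(a, b)
})

test_that("label counts are deterministic, not Bernoulli", {
  ds <- synthesize_patches(gen_params(n = 1000, pos_fraction = 0.595,
                                      seed = 9, blob_count = 0))
  expect_equal(sum(ds$labels == 1), 595)
  expect_equal(ds$pos_fraction, 0.595)
  ds2 <- synthesize_patches(gen_params(n = 10, pos_fraction = 0.5, seed = 9,
                                       blob_count = 0))
  expect_equal(sum(ds2$labels == 1), 5)
  expect_equal(sum(ds2$labels == 0), 5)
})

test_that("datasets written to disk are byte-identical across runs", {
  p <- gen_params(n = 8, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_dataset(p, d1)
  m2 <- make_dataset(p, d2)
  expect_identical(readBin(file.path(d1, "labels.csv"), "raw", 10000),
                   readBin(file.path(d2, "labels.csv"), "raw", 10000))
  for (f in m1$path) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_equal(readLines(file.path(d1, "labels.csv"), n = 1), "id,label")
  expect_error(make_dataset(gen_params(n = 1, seed = 1), d1), "n >= 2")
})

test_that("a written dataset loads back to the generated patches", {
  p <- gen_params(n = 6, seed = 14)
  d <- withr::local_tempdir()
  make_dataset(p, d)
  loaded <- load_dataset(d)
  in_mem <- synthesize_patches(p)
  expect_identical(loaded$labels, in_mem$labels)
  expect_identical(loaded$ids, in_mem$ids)
  # PNG storage is 8-bit: equal up to quantization
  expect_lt(max(abs(loaded$images - in_mem$images)), 1 / 255)
})

test_that("the center probe finds signal only in the central window", {
  for (seed in 1:3) {
    ds <- tiny_ds(1000, seed = seed)
    acc <- center_signal_probe(ds)
    expect_gte(acc[["acc_center"]], 0.9)
    expect_lte(acc[["acc_periphery"]], 0.6)
    expect_gte(acc[["acc_center"]] - acc[["acc_periphery"]], 0.3)
  }
})

test_that("the probe is at chance without signal or with shuffled labels", {
  ds0 <- tiny_ds(400, seed = 4, signal_strength = 0)
  acc0 <- center_signal_probe(ds0)
  expect_lt(abs(acc0[["acc_center"]] - 0.5), 0.1)

  ds <- tiny_ds(400, seed = 1)
  shuffled <- ds
  set.seed(123)
  shuffled$labels <- sample(ds$labels)
  accs <- center_signal_probe(shuffled)
  expect_lt(abs(accs[["acc_center"]] - 0.5), 0.1)

  onecls <- ds
  onecls$labels <- rep(1L, length(ds$labels))
  expect_error(center_signal_probe(onecls), "both classes")
  small <- synthesize_patches(gen_params(n = 50, seed = 2))
  expect_error(center_signal_probe(small), "at least 200")
})
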