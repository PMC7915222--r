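test_that("confusion counts partition the samples and reject bad input", {
  cc <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 2, TN = 1, FP = 0, FN = 0))
  cc <- confusion(c(1, 1, 1), c(1, 0, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1, TN = 0, FP = 2, FN = 0))
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 3)
  expect_error(confusion(numeric(0), numeric(0)), "empty")
  expect_error(confusion(c(1, 0), c(1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("threshold metrics match their defining formulas", {
  # TP=3, TN=4, FP=1, FN=2 built from explicit label vectors
  cc <- confusion(pred  = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1),
                  truth = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(accuracy(cc), 0.7)
  expect_equal(sensitivity(cc), 0.6)
  expect_equal(specificity(cc), 0.8)
  expect_equal(f_measure(cc), 6 / 9)
})

test_that("metric edge cases: perfect, always-wrong, undefined", {
  perfect <- structure(list(TP = 5, TN = 5, FP = 0, FN = 0),
                       class = "patchboost_confusion")
  expect_equal(accuracy(perfect), 1)
  expect_equal(sensitivity(perfect), 1)
  expect_equal(f_measure(perfect), 1)
  wrong <- structure(list(TP = 0, TN = 0, FP = 3, FN = 2),
                     class = "patchboost_confusion")
  expect_equal(accuracy(wrong), 0)
  nopos <- structure(list(TP = 0, TN = 4, FP = 0, FN = 0),
                     class = "patchboost_confusion")
  expect_true(is.na(sensitivity(nopos)))
  expect_equal(specificity(nopos), 1)
})

test_that("F-measure equals the harmonic mean of precision and recall", {
  set.seed(7)
  for (i in 1:20) {
    cc <- structure(as.list(c(TP = sample(1:20, 1), TN = sample(0:20, 1),
                              FP = sample(0:20, 1), FN = sample(0:20, 1))),
                    class = "patchboost_confusion")
    prec <- cc$TP / (cc$TP + cc$FP)
    rec <- cc$TP / (cc$TP + cc$FN)
    expect_equal(f_measure(cc), 2 * prec * rec / (prec + rec))
  }
})

test_that("accuracy decomposes as the class-weighted mean of SEN and SPE", {
  set.seed(8)
  for (i in 1:20) {
    cc <- structure(as.list(c(TP = sample(1:15, 1), TN = sample(1:15, 1),
                              FP = sample(0:15, 1), FN = sample(0:15, 1))),
                    class = "patchboost_confusion")
    P <- cc$TP + cc$FN
    N <- cc$TN + cc$FP
    expect_equal(accuracy(cc),
                 (sensitivity(cc) * P + specificity(cc) * N) / (P + N))
  }
})

test_that("AUC handles separation, ties and the worked example", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auc_score(c(0.9, 0.4, 0.6, 0.1), c(1, 0, 1, 0)), 1)
  expect_equal(auc_score(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the exhaustive pair-counting oracle", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    # coarse score grid forces frequent ties
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(auc_score(scores, labels), pairwise_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms and
           matches an independent implementation", {
  set.seed(12)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a <- auc_score(scores, labels)
  expect_equal(auc_score(qlogis(scores), labels), a)
  expect_equal(auc_score(scores^3, labels), a)
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE))))
})

test_that("metrics_report flags undefined metrics and round-trips JSON", {
  rep1 <- metrics_report(c(0.9, 0.8, 0.3, 0.6), c(1, 1, 0, 0))
  expect_equal(rep1$ACC, 0.75)
  expect_equal(rep1$AUC, 1)
  expect_equal(rep1$n, 4)
  expect_identical(rep1$flagged, character(0))
  rt <- metrics_from_json(metrics_to_json(rep1))
  expect_equal(rt$ACC, rep1$ACC)
  expect_equal(rt$counts, rep1$counts)

  # single-class labels: AUC undefined but flagged, threshold metrics fine
  rep2 <- metrics_report(c(0.9, 0.8), c(1, 1))
  expect_true(is.na(rep2$AUC))
  expect_true("AUC" %in% rep2$flagged)
  expect_equal(rep2$ACC, 1)
  rt2 <- metrics_from_json(metrics_to_json(rep2))
  expect_true(is.na(rt2$AUC))
})

test_that("CSV row uses the standard column order as percentages", {
  rep1 <- metrics_report(c(0.9, 0.8, 0.3, 0.6), c(1, 1, 0, 0))
  expect_equal(metrics_csv_row(rep1), "75.00,100.00,100.00,50.00,80.00")
})

test_that("aggregation reports sd only with two or more runs", {
  r1 <- metrics_report(c(0.9, 0.2), c(1, 0))
  r2 <- metrics_report(c(0.6, 0.4), c(1, 0))
  one <- aggregate_metrics(list(r1))
  expect_null(one$sd)
  two <- aggregate_metrics(list(r1, r2))
  expect_false(is.null(two$sd))
  expect_equal(two$mean[two$metric == "ACC"], 1)
})
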