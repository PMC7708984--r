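test_that("confusion counts follow the four-count convention", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cc$n_pos, 2); expect_equal(cc$n_neg, 2)
  expect_equal(cc$fn, 1); expect_equal(cc$fp, 1)
  all_right <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(all_right$fn + all_right$fp, 0)
  all_wrong <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(all_wrong$fn, all_wrong$n_pos)
  expect_equal(all_wrong$fp, all_wrong$n_neg)
  expect_error(confusion_counts(c(1, 0), c(1)), class = "ac4c_validation_error")
})

test_that("threshold metrics reproduce hand-computed values", {
  cc <- structure(list(n_pos = 60, n_neg = 100, fn = 10, fp = 10),
                  class = "ac4c_confusion")
  expect_equal(accuracy(cc), 0.875)
  expect_equal(sensitivity(cc), 5 / 6)
  expect_equal(specificity(cc), 0.9)
  expect_equal(mcc(cc), 4400 / 6000)
  perfect <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(accuracy(perfect), 1); expect_equal(mcc(perfect), 1)
  inverted <- confusion_counts(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(accuracy(inverted), 0); expect_equal(mcc(inverted), -1)
})

test_that("undefined metrics raise a typed signal rather than a sentinel", {
  no_pos <- structure(list(n_pos = 0L, n_neg = 5L, fn = 0L, fp = 1L),
                      class = "ac4c_confusion")
  expect_error(sensitivity(no_pos), class = "ac4c_undefined_metric")
  expect_error(mcc(no_pos), class = "ac4c_undefined_metric")
  all_neg_pred <- confusion_counts(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_error(mcc(all_neg_pred), class = "ac4c_undefined_metric")
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), class = "ac4c_undefined_metric")
  expect_error(auprc(c(0, 0), c(0.2, 0.3)), class = "ac4c_undefined_metric")
  # the six-metric summary degrades gracefully: NA for the undefined label
  # metric, defined values elsewhere
  sc <- score_predictions(c(1, 1, 0, 0), c(0.4, 0.3, 0.2, 0.1), threshold = 0.5)
  expect_true(is.na(sc[["mcc"]]))
  expect_equal(sc[["auroc"]], 1)
})

test_that("four-count MCC equals the standard formula over an exhaustive sweep", {
  checked <- 0L
  for (n_pos in 1:20) for (n_neg in 1:20) {
    fn <- rep(0:n_pos, each = n_neg + 1L)
    fp <- rep(0:n_neg, times = n_pos + 1L)
    num <- 1 - (fn / n_pos + fp / n_neg)
    den2 <- (1 + (fp - fn) / n_pos) * (1 + (fn - fp) / n_neg)
    keep <- den2 > 0
    got <- num[keep] / sqrt(den2[keep])
    want <- mapply(oracle_mcc, n_pos, n_neg, fn[keep], fp[keep])
    expect_equal(got, unname(want), tolerance = 1e-12)
    checked <- checked + sum(keep)
  }
  expect_gt(checked, 10000)
  # spot-check that the vectorized sweep matches the exported function
  cc <- structure(list(n_pos = 7L, n_neg = 13L, fn = 2L, fp = 4L),
                  class = "ac4c_confusion")
  expect_equal(mcc(cc), oracle_mcc(7, 13, 2, 4))
})

test_that("accuracy is the class-size-weighted mean of SN and SP", {
  set.seed(4)
  for (i in 1:50) {
    n_pos <- sample(1:30, 1); n_neg <- sample(1:30, 1)
    cc <- structure(list(n_pos = n_pos, n_neg = n_neg,
                         fn = sample(0:n_pos, 1), fp = sample(0:n_neg, 1)),
                    class = "ac4c_confusion")
    expect_equal(accuracy(cc),
                 (n_pos * sensitivity(cc) + n_neg * specificity(cc)) / (n_pos + n_neg))
  }
})

test_that("AUROC equals the pairwise-ordering oracle, with ties at half", {
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)), 0.75)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  set.seed(21)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(1:2, 1))   # coarse rounding forces ties
    expect_equal(auroc(y, s), oracle_auroc(y, s))
  }
})

test_that("AUROC cross-checks against an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- runif(n)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(auroc(y, s), ref, tolerance = 1e-12)
  }
})

test_that("AUPRC is the non-interpolated step area", {
  # hand-computed: recall steps at thresholds 0.9 (precision 1) and 0.4
  # (precision 2/3); the other thresholds add no recall
  y <- c(1, 0, 1, 0); s <- c(0.9, 0.8, 0.4, 0.1)
  expect_equal(auprc(y, s), 0.5 * 1 + 0.5 * (2 / 3))
  # perfect ranking: AP = 1
  expect_equal(auprc(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1)
  # constant scores: one block, AP = prevalence
  expect_equal(auprc(c(1, 0, 0, 0), rep(0.3, 4)), 0.25)
  # brute-force threshold-sweep oracle on random vectors
  set.seed(13)
  for (i in 1:40) {
    n <- sample(5:25, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 1)
    thr <- sort(unique(s), decreasing = TRUE)
    prev_r <- 0; ap <- 0
    for (t in thr) {
      tp <- sum(y == 1 & s >= t); called <- sum(s >= t)
      r <- tp / sum(y == 1); p <- tp / called
      ap <- ap + (r - prev_r) * p; prev_r <- r
    }
    expect_equal(auprc(y, s), ap)
  }
})

test_that("stratified folds are balanced, disjoint, exhaustive and seeded", {
  y <- rep(c(1, 0), c(1160, 10855))
  f <- stratified_kfold(y, k = 5, seed = 42)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k & y == 1), 232)
    expect_equal(sum(f == k & y == 0), 2171)
  }
  expect_identical(as.integer(stratified_kfold(y, 5, 42)),
                   as.integer(f))
  expect_false(identical(as.integer(stratified_kfold(y, 5, 43)),
                         as.integer(f)))
  # exact division at small n
  f2 <- stratified_kfold(rep(c(1, 0), each = 10), k = 5, seed = 1)
  expect_true(all(table(f2) == 4))
  # uneven classes: per-fold counts differ by at most 1
  y3 <- rep(c(1, 0), c(13, 29))
  f3 <- stratified_kfold(y3, k = 5, seed = 3)
  for (cl in 0:1) {
    counts <- table(f3[y3 == cl])
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_error(stratified_kfold(rep(c(1, 0), c(3, 50)), k = 5),
               class = "ac4c_validation_error")
})

test_that("cross-validation separates enriched positives and is chance on shuffled labels", {
  d <- quick_dataset(n_pos = 25, n_neg = 75, length = 51, enrichment = 6)
  X <- encode_dataset(d$sequences, "eiip_pseeiip")
  cv <- cross_validate(X, d$labels, config = quick_config(), k = 5, seed = 7)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(unname(cv$mean), unname(colMeans(as.matrix(cv$per_fold))))
  expect_gte(cv$mean[["auroc"]], 0.95)
  set.seed(99); y_shuf <- sample(d$labels)
  cv0 <- cross_validate(X, y_shuf, config = quick_config(), k = 5, seed = 7)
  expect_lt(abs(cv0$mean[["auroc"]] - 0.5), 0.15)
  # JSON serialization carries the per-fold table
  js <- jsonlite::fromJSON(cv_to_json(cv))
  expect_equal(nrow(js$per_fold), 5)
  expect_equal(js$mean$auroc, cv$mean[["auroc"]])
})
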