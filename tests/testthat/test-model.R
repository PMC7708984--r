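test_that("default configuration carries the tuned hyperparameter set", {
  cfg <- ac4c_config()
  expect_equal(cfg$n_estimators, 1200L)
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$min_child_weight, 5)
  expect_equal(cfg$max_depth, 5L)
  expect_equal(cfg$colsample_bytree, 0.8)
  expect_equal(cfg$gamma, 5)
  expect_equal(cfg$subsample, 0.8)
  expect_equal(cfg$scale_pos_weight, 6)
})

test_that("training is deterministic and separates the enriched fixture", {
  d <- quick_dataset()
  X <- encode_dataset(d$sequences, "eiip_pseeiip")
  m1 <- ac4c_fit(X, d$labels, config = quick_config())
  m2 <- ac4c_fit(X, d$labels, config = quick_config())
  expect_identical(predict_proba(m1, X), predict_proba(m2, X))
  expect_gte(auroc(d$labels, predict_proba(m1, X)), 0.99)
  # different seed changes the (subsampled) ensemble
  m3 <- ac4c_fit(X, d$labels, config = quick_config(seed = 7))
  expect_false(identical(predict_proba(m1, X), predict_proba(m3, X)))
})

test_that("probability and label predictions obey their contracts", {
  d <- quick_dataset()
  m <- ac4c_fit(d$sequences, d$labels, scheme = "eiip_pseeiip",
                config = quick_config())
  X <- encode_dataset(d$sequences, "eiip_pseeiip")
  p <- predict_proba(m, X)
  expect_true(all(p >= 0 & p <= 1))
  # permutation of rows permutes scores identically; duplicates score equally
  perm <- sample(nrow(X))
  expect_equal(unname(predict_proba(m, X[perm, ])), unname(p[perm]))
  expect_equal(unname(predict_proba(m, X[c(1, 1), ]))[1],
               unname(predict_proba(m, X[c(1, 1), ]))[2])
  # label = probability >= threshold; raw sequences accepted too
  lab <- predict(m, d$sequences, type = "class", threshold = 0.5)
  expect_identical(unname(lab), unname(as.integer(p >= 0.5)))
  expect_true(all(predict(m, X, type = "class", threshold = 1e-9) == 1))
  expect_error(predict(m, X, type = "class", threshold = 0),
               class = "ac4c_validation_error")
  # margin scale links to probability through the logistic function
  mar <- predict(m, X, type = "margin")
  expect_equal(unname(1 / (1 + exp(-mar))), unname(p), tolerance = 1e-6)
})

test_that("training rejects degenerate inputs and incompatible widths", {
  d <- quick_dataset(n_pos = 5, n_neg = 10, length = 15)
  X <- encode_dataset(d$sequences, "kmer")
  expect_error(ac4c_fit(X, rep(1, nrow(X)), config = quick_config()),
               class = "ac4c_validation_error")
  m <- ac4c_fit(X, d$labels, config = quick_config())
  expect_error(predict_proba(m, X[, 1:10]), class = "ac4c_validation_error")
  Xwrong <- encode_dataset(d$sequences, "eiip_pseeiip")
  expect_error(predict_proba(m, Xwrong), class = "ac4c_validation_error")
})

test_that("a saved model reloads and reproduces predictions bit-identically", {
  d <- quick_dataset(n_pos = 8, n_neg = 24, length = 21)
  X <- encode_dataset(d$sequences, "eiip_pseeiip")
  m <- ac4c_fit(X, d$labels, config = quick_config())
  path <- withr::local_tempfile(fileext = ".rds")
  ac4c_save(m, path)
  back <- ac4c_load(path)
  expect_identical(predict_proba(back, X), predict_proba(m, X))
  expect_identical(back$feature_names, m$feature_names)
  expect_identical(back$fingerprint, m$fingerprint)
})

test_that("raising scale_pos_weight does not lower training sensitivity", {
  d <- quick_dataset(n_pos = 15, n_neg = 85, length = 33, enrichment = 2,
                     seed = 5)
  X <- encode_dataset(d$sequences, "eiip_pseeiip")
  sn_at <- vapply(c(1, 6, 20), function(w) {
    m <- ac4c_fit(X, d$labels,
                  config = quick_config(scale_pos_weight = w, n_estimators = 40))
    cc <- confusion_counts(d$labels, predict(m, X, type = "class"))
    sensitivity(cc)
  }, numeric(1))
  expect_true(all(diff(sn_at) >= 0))
})

test_that("grid search is exhaustive, tie-stable, and avoids degenerate configs", {
  d <- quick_dataset(n_pos = 15, n_neg = 45, length = 33)
  X <- encode_dataset(d$sequences, "eiip_pseeiip")
  single <- grid_search(X, d$labels, list(max_depth = 4L), k = 3, seed = 2,
                        base = quick_config())
  expect_equal(single$max_depth, 4L)
  grid <- list(max_depth = c(5L, 1L), n_estimators = c(60L, 1L))
  won <- grid_search(X, d$labels, grid, k = 3, seed = 2, base = quick_config())
  res <- attr(won, "results")
  expect_equal(nrow(res), 4)   # full Cartesian product
  expect_false(won$n_estimators == 1L && won$max_depth == 1L)
  expect_error(grid_search(X, d$labels, list(), base = quick_config()),
               class = "ac4c_validation_error")
  expect_error(grid_search(X, d$labels, list(max_depth = integer(0)),
                           base = quick_config()),
               class = "ac4c_validation_error")
  expect_error(grid_search(X, d$labels, list(bogus = 1),
                           base = quick_config()),
               class = "ac4c_validation_error")
})

test_that("all four baselines fit and expose the probability contract", {
  d <- quick_dataset(n_pos = 15, n_neg = 35, length = 21)
  X <- encode_dataset(d$sequences, "kmer")
  for (b in c("logistic_regression", "gaussian_nb", "adaboost", "random_forest")) {
    fit <- fit_baseline(b, X, d$labels, seed = 3)
    p <- predict_proba(fit, X)
    expect_length(p, nrow(X))
    expect_true(all(p >= 0 & p <= 1))
    # stochastic baselines reproduce under the same seed
    p2 <- predict_proba(fit_baseline(b, X, d$labels, seed = 3), X)
    expect_equal(unname(p), unname(p2))
  }
  expect_error(fit_baseline("svm", X, d$labels), class = "ac4c_validation_error")
})

test_that("Gaussian NB reaches AUROC 1 on a perfectly separated feature", {
  X <- cbind(feat = c(rnorm(20, -5, 0.3), rnorm(20, 5, 0.3)))
  y <- rep(c(0, 1), each = 20)
  fit <- fit_baseline("gaussian_nb", X, y, seed = 1)
  expect_equal(auroc(y, predict_proba(fit, X)), 1)
})

test_that("comparison harness crosses classifiers with encodings", {
  d <- quick_dataset(n_pos = 15, n_neg = 45, length = 21, enrichment = 6)
  cmp <- compare_all(d$sequences, d$labels, k = 3, seed = 5,
                     config = quick_config(),
                     schemes = c("kmer", "eiip_pseeiip"),
                     classifiers = c("xgboost", "gaussian_nb"))
  expect_equal(nrow(cmp), 4)
  expect_identical(names(cmp)[3:8], c("acc", "sn", "sp", "mcc", "auroc", "auprc"))
  # boosted trees on the enriched fixture beat the shuffled-label control
  set.seed(31); y_shuf <- sample(d$labels)
  cv_real <- cross_validate(encode_dataset(d$sequences, "eiip_pseeiip"),
                            d$labels, config = quick_config(), k = 3, seed = 5)
  cv_null <- cross_validate(encode_dataset(d$sequences, "eiip_pseeiip"),
                            y_shuf, config = quick_config(), k = 3, seed = 5)
  expect_gte(cv_real$mean[["auprc"]], cv_null$mean[["auprc"]])
  # JSON round-trip preserves the table numerically
  path <- withr::local_tempfile(fileext = ".json")
  comparison_to_json(cmp, path)
  back <- comparison_from_json(path)
  expect_equal(back$auroc, cmp$auroc, tolerance = 1e-12)
  expect_identical(back$classifier, cmp$classifier)
})
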