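# The gradient-boosted site classifier and the baseline-comparison harness.

#' Hyperparameter configuration for the boosted-tree classifier
#'
#' Defaults are the grid-search optimum for the 1:9-imbalanced ac4C
#' benchmark: 1200 trees, learning rate 0.01, min_child_weight 5, max_depth
#' 5, colsample_bytree 0.8, gamma 5, subsample 0.8, scale_pos_weight 6.
#' Imbalance is handled through `scale_pos_weight` (gradient reweighting of
#' the minority class), not by resampling.
#'
#' @param n_estimators Number of boosting rounds.
#' @param learning_rate Shrinkage per round (eta).
#' @param min_child_weight Minimum hessian sum per leaf.
#' @param max_depth Maximum tree depth.
#' @param colsample_bytree Column subsample fraction per tree, in (0, 1].
#' @param gamma Minimum loss reduction to split.
#' @param subsample Row subsample fraction per tree, in (0, 1].
#' @param scale_pos_weight Loss weight multiplier for the positive class.
#' @param seed Integer seed for the booster's subsampling RNG.
#' @return An object of class `ac4c_config`.
#' @export
ac4c_config <- function(n_estimators = 1200L, learning_rate = 0.01,
                        min_child_weight = 5, max_depth = 5L,
                        colsample_bytree = 0.8, gamma = 5, subsample = 0.8,
                        scale_pos_weight = 6, seed = 42L) {
  stopifnot(n_estimators >= 1, learning_rate > 0,
            colsample_bytree > 0, colsample_bytree <= 1,
            gamma >= 0, subsample > 0, subsample <= 1, scale_pos_weight > 0)
  structure(list(
    n_estimators = as.integer(n_estimators), learning_rate = learning_rate,
    min_child_weight = min_child_weight, max_depth = as.integer(max_depth),
    colsample_bytree = colsample_bytree, gamma = gamma, subsample = subsample,
    scale_pos_weight = scale_pos_weight, seed = as.integer(seed)
  ), class = "ac4c_config")
}

#' @export
print.ac4c_config <- function(x, ...) {
  cat("boosted-tree configuration:\n")
  for (n in names(x)) cat(sprintf("  %-18s %s\n", n, format(x[[n]])))
  invisible(x)
}

as_feature_matrix <- function(x, scheme) {
  if (is.character(x)) encode_dataset(x, scheme) else x
}

#' Fit the ac4C site classifier
#'
#' Trains a gradient-boosted decision-tree ensemble (binary logistic
#' objective) on encoded sequence windows. Training is deterministic given
#' the data and `config$seed`, and single-threaded by default so results are
#' reproducible across machines.
#'
#' @param x Named character vector of normalized sequences, or a numeric
#'   feature matrix from [encode_dataset()].
#' @param y Binary 0/1 labels (1 = ac4C site), aligned with `x`.
#' @param scheme Encoding scheme used when `x` holds raw sequences.
#' @param config An [ac4c_config()].
#' @param nthread Number of training threads.
#' @return An object of class `ac4c_model` holding the fitted booster, the
#'   configuration, scheme, feature names, training class counts, and the
#'   per-feature quartiles used by [local_explanation()].
#' @export
ac4c_fit <- function(x, y, scheme = "eiip_pseeiip", config = ac4c_config(),
                     nthread = 1L) {
  X <- as_feature_matrix(x, scheme)
  if (nrow(X) == 0L) abort_validation("no training rows")
  if (nrow(X) != length(y)) abort_validation("x rows and y must be aligned")
  if (!all(y %in% c(0, 1))) abort_validation("labels must be binary 0/1")
  if (length(unique(y)) < 2L)
    abort_validation("training requires both classes to be present")
  dtrain <- xgboost::xgb.DMatrix(unname(X), label = y, nthread = nthread)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      eta = config$learning_rate,
      max_depth = config$max_depth,
      min_child_weight = config$min_child_weight,
      gamma = config$gamma,
      subsample = config$subsample,
      colsample_bytree = config$colsample_bytree,
      scale_pos_weight = config$scale_pos_weight,
      nthread = nthread,
      seed = config$seed
    ),
    data = dtrain, nrounds = config$n_estimators, verbose = 0
  )
  structure(list(
    booster_raw = xgboost::xgb.save.raw(booster),
    config = config,
    scheme = attr(X, "scheme") %||% scheme,
    feature_names = colnames(X),
    fingerprint = c(n_pos = sum(y == 1), n_neg = sum(y == 0)),
    feature_quartiles = t(apply(X, 2L, stats::quantile,
                                probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
  ), class = "ac4c_model")
}

# materialize the booster handle (kept as raw bytes so the model object
# serializes with saveRDS and reloads bit-identically)
model_booster <- function(model) xgboost::xgb.load.raw(model$booster_raw)

check_compatible <- function(model, X) {
  if (ncol(X) != length(model$feature_names))
    abort_validation(sprintf("feature width %d does not match the model's %d",
                             ncol(X), length(model$feature_names)))
  sc <- attr(X, "scheme")
  if (!is.null(sc) && !identical(sc, model$scheme))
    abort_validation(sprintf("matrix scheme '%s' does not match the model's '%s'",
                             sc, model$scheme))
  invisible(TRUE)
}

#' Predicted site probabilities
#'
#' Generic scoring contract shared by the boosted-tree model and the
#' baseline classifiers: one probability per row, in input order.
#'
#' @param object A fitted classifier.
#' @param X Feature matrix compatible with the classifier.
#' @param ... Passed to methods.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(object, X, ...) UseMethod("predict_proba")

#' @export
predict_proba.ac4c_model <- function(object, X, ...) {
  check_compatible(object, X)
  p <- stats::predict(model_booster(object), unname(as.matrix(X)))
  names(p) <- rownames(X)
  p
}

#' Predict method for ac4C site models
#'
#' @param object An `ac4c_model`.
#' @param newdata Sequences (character) or feature matrix.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 calls,
#'   `"margin"` for log-odds.
#' @param threshold Probability cutoff for `type = "class"`; a sequence is
#'   called a site when its probability is >= threshold.
#' @param ... Unused.
#' @return Numeric vector (probabilities or margins) or integer 0/1 vector.
#' @export
predict.ac4c_model <- function(object, newdata, type = c("prob", "class", "margin"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata, object$scheme)
  if (type == "margin") {
    check_compatible(object, X)
    m <- stats::predict(model_booster(object), unname(as.matrix(X)),
                        outputmargin = TRUE)
    names(m) <- rownames(X)
    return(m)
  }
  p <- predict_proba(object, X)
  if (type == "prob") return(p)
  if (threshold <= 0 || threshold >= 1)
    abort_validation("threshold must lie in (0, 1)")
  stats::setNames(as.integer(p >= threshold), names(p))
}

#' @export
print.ac4c_model <- function(x, ...) {
  cat(sprintf("ac4C site classifier (gradient-boosted trees)\n"))
  cat(sprintf("  scheme: %s (%d features)\n", x$scheme, length(x$feature_names)))
  cat(sprintf("  trained on %d sites / %d non-sites (imbalance 1:%.1f)\n",
              x$fingerprint["n_pos"], x$fingerprint["n_neg"],
              x$fingerprint["n_neg"] / max(1, x$fingerprint["n_pos"])))
  cat(sprintf("  %d trees, depth %d, eta %g, scale_pos_weight %g, seed %d\n",
              x$config$n_estimators, x$config$max_depth, x$config$learning_rate,
              x$config$scale_pos_weight, x$config$seed))
  invisible(x)
}

#' @export
summary.ac4c_model <- function(object, ...) {
  print(object)
  cat("\nconfiguration:\n")
  print(object$config)
  invisible(object)
}

#' Save / load a fitted model bundle
#'
#' The bundle carries the booster bytes plus scheme, feature names,
#' configuration and training fingerprint, so loading validates
#' compatibility and reproduces predictions bit-identically.
#'
#' @param model An `ac4c_model`.
#' @param path File path for the bundle.
#' @return `ac4c_save` returns `path` invisibly; `ac4c_load` returns the
#'   model.
#' @export
ac4c_save <- function(model, path) {
  if (!inherits(model, "ac4c_model")) abort_validation("not an ac4c_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname ac4c_save
#' @export
ac4c_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ac4c_model")) abort_validation("file is not a model bundle")
  model
}

#' Exhaustive grid search over boosted-tree hyperparameters
#'
#' Scores every configuration in the Cartesian product of the supplied axes
#' by mean cross-validated metric and returns the winner; ties go to the
#' higher metric, then to the earlier grid position.
#'
#' @inheritParams cross_validate
#' @param grid Named list mapping [ac4c_config()] argument names to value
#'   vectors.
#' @param objective Metric to maximize: one of acc, sn, sp, mcc, auroc,
#'   auprc. Default `"auprc"` — the headline metric under 1:9 imbalance.
#' @param base Configuration supplying values for axes absent from `grid`.
#' @return The winning `ac4c_config`, with attributes `objective_value` and
#'   `results` (per-candidate data frame).
#' @export
grid_search <- function(x, y, grid, k = 5L, seed = 42L,
                        objective = "auprc", scheme = "eiip_pseeiip",
                        base = ac4c_config()) {
  if (!is.list(grid) || length(grid) == 0L)
    abort_validation("grid must be a non-empty named list")
  if (any(lengths(grid) == 0L))
    abort_validation("every grid axis must have at least one value")
  bad <- setdiff(names(grid), names(base))
  if (length(bad))
    abort_validation(sprintf("unknown hyperparameter(s): %s", paste(bad, collapse = ", ")))
  objective <- match.arg(objective, c("acc", "sn", "sp", "mcc", "auroc", "auprc"))
  X <- as_feature_matrix(x, scheme)
  cand <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cfg <- base
    for (nm in names(cand)) cfg[[nm]] <- cand[[nm]][i]
    cfg <- do.call(ac4c_config, cfg[names(formals(ac4c_config))])
    cv <- cross_validate(X, y, config = cfg, k = k, seed = seed)
    scores[i] <- cv$mean[[objective]]
  }
  best <- which.max(scores)   # first maximum = earlier grid order on ties
  cfg <- base
  for (nm in names(cand)) cfg[[nm]] <- cand[[nm]][best]
  winner <- do.call(ac4c_config, cfg[names(formals(ac4c_config))])
  attr(winner, "objective_value") <- scores[best]
  attr(winner, "results") <- cbind(cand, objective = scores)
  winner
}

# ---- baseline classifiers ---------------------------------------------------

BASELINES <- c("logistic_regression", "gaussian_nb", "adaboost", "random_forest")

#' Fit a baseline classifier
#'
#' Reference classifiers for the comparison harness, each fit with its
#' library defaults and a pinned seed: penalized-free logistic regression
#' (`glm`), Gaussian naive Bayes (`e1071::naiveBayes`), discrete AdaBoost
#' over depth-1 `rpart` stumps (50 rounds), and `randomForest` with default
#' settings. All expose the [predict_proba()] contract.
#'
#' @param name One of `"logistic_regression"`, `"gaussian_nb"`,
#'   `"adaboost"`, `"random_forest"`.
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param seed Integer seed for the stochastic baselines.
#' @return An object of class `ac4c_baseline`.
#' @export
fit_baseline <- function(name, X, y, seed = 42L) {
  if (!name %in% BASELINES)
    abort_validation(sprintf("unknown baseline '%s' (choose from %s)",
                             name, paste(BASELINES, collapse = ", ")))
  if (length(unique(y)) < 2L)
    abort_validation("training requires both classes to be present")
  X <- as.matrix(X)
  colnames(X) <- sprintf("f%d", seq_len(ncol(X)))   # syntactic names for the fitters
  fit <- with_seed(seed, switch(name,
    logistic_regression = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    gaussian_nb = {
      keep <- apply(X, 2L, stats::var) > 0
      list(nb = e1071::naiveBayes(X[, keep, drop = FALSE], factor(y, levels = c(0, 1))),
           keep = keep)
    },
    adaboost = adaboost_fit(X, y, n_rounds = 50L),
    random_forest = randomForest::randomForest(X, factor(y, levels = c(0, 1)))
  ))
  structure(list(name = name, fit = fit, p = ncol(X)), class = "ac4c_baseline")
}

#' @export
predict_proba.ac4c_baseline <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$p)
    abort_validation("feature width does not match the baseline model")
  colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  p <- switch(object$name,
    logistic_regression = {
      df <- as.data.frame(X)
      suppressWarnings(unname(stats::predict(object$fit, newdata = df, type = "response")))
    },
    gaussian_nb = {
      pr <- stats::predict(object$fit$nb, X[, object$fit$keep, drop = FALSE],
                           type = "raw")
      unname(pr[, "1"])
    },
    adaboost = adaboost_predict(object$fit, X),
    random_forest = unname(stats::predict(object$fit, X, type = "prob")[, "1"])
  )
  names(p) <- rownames(X)
  p
}

#' @export
print.ac4c_baseline <- function(x, ...) {
  cat(sprintf("baseline classifier: %s (%d features)\n", x$name, x$p))
  invisible(x)
}

# Discrete AdaBoost (SAMME with two classes) over depth-1 rpart stumps.
# Weighted error per round; alpha = log((1-err)/err); weights renormalized.
adaboost_fit <- function(X, y, n_rounds = 50L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1, 1, -1)
  df <- data.frame(X)
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(factor(yy) ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1L, cp = -1,
                                                       minsplit = 2L, xval = 0L))
    pred <- as.numeric(as.character(stats::predict(fit, df, type = "class")))
    err <- sum(w[pred != yy])
    if (err <= 0) { used <- used + 1L; stumps[[used]] <- fit; alphas[used] <- 10; break }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    used <- used + 1L
    stumps[[used]] <- fit
    alphas[used] <- alpha
  }
  if (used == 0L) {  # no stump beat chance; fall back to the class prior
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)], prior = mean(y))
}

adaboost_predict <- function(fit, X) {
  if (length(fit$stumps) == 0L) return(rep(fit$prior, nrow(X)))
  df <- data.frame(X)
  F <- rep(0, nrow(X))
  for (m in seq_along(fit$stumps)) {
    pred <- as.numeric(as.character(stats::predict(fit$stumps[[m]], df, type = "class")))
    F <- F + fit$alphas[m] * pred
  }
  1 / (1 + exp(-2 * F))   # logistic link on the additive margin
}

#' Cross-validated comparison of classifiers across encodings
#'
#' Crosses the boosted-tree model and the four baselines with the four
#' benchmark encodings (one-hot, NCP+ND, k-mer, EIIP+PseEIIP), scoring each
#' cell by stratified k-fold cross-validation on all six metrics. Baselines
#' run with library defaults and a pinned seed, so their rows reflect
#' untuned reference performance.
#'
#' @param seqs Named character vector of normalized, equal-length sequences.
#' @param y Binary 0/1 labels.
#' @param k Folds.
#' @param seed Integer seed.
#' @param config [ac4c_config()] for the boosted-tree rows.
#' @param schemes Encoding schemes to include.
#' @param classifiers Classifiers to include (`"xgboost"` plus baselines).
#' @return An `ac4c_comparison` data frame: classifier, scheme, and the six
#'   mean metrics.
#' @export
compare_all <- function(seqs, y, k = 5L, seed = 42L, config = ac4c_config(),
                        schemes = c("onehot", "ncp_nd", "kmer", "eiip_pseeiip"),
                        classifiers = c("xgboost", BASELINES)) {
  rows <- list()
  for (sc in schemes) {
    X <- encode_dataset(seqs, sc)
    for (clf in classifiers) {
      cv <- if (clf == "xgboost") {
        cross_validate(X, y, config = config, k = k, seed = seed)
      } else {
        cross_validate(X, y, k = k, seed = seed,
                       fit_fun = function(Xtr, ytr, s) fit_baseline(clf, Xtr, ytr, s))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(classifier = clf, scheme = sc, t(cv$mean))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ac4c_comparison", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "k") <- k
  out
}

#' Serialize / restore a comparison table as JSON
#'
#' @param cmp An `ac4c_comparison` data frame.
#' @param path Optional output path.
#' @return JSON string, or (for `comparison_from_json`) the restored table.
#' @export
comparison_to_json <- function(cmp, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(cmp), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname comparison_to_json
#' @export
comparison_from_json <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "") else path
  out <- jsonlite::fromJSON(txt)
  class(out) <- c("ac4c_comparison", "data.frame")
  out
}
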