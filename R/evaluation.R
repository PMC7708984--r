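# Imbalance-aware evaluation: four-count confusion summaries, the Chou-form
# threshold metrics, threshold-free AUROC / AUPRC, and the stratified
# cross-validation protocol used by the benchmark.

#' Four-count confusion summary
#'
#' The four quantities of the Chou convention: `n_pos` (true ac4C sites,
#' N+), `n_neg` (true non-sites, N-), `fn` (ac4C sites called non-sites,
#' N-+), `fp` (non-sites called ac4C, N+-).
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return An object of class `ac4c_confusion`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    abort_validation("y_true and y_pred must have equal length >= 1")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    abort_validation("labels must be binary 0/1")
  structure(list(
    n_pos = sum(y_true == 1),
    n_neg = sum(y_true == 0),
    fn = sum(y_true == 1 & y_pred == 0),
    fp = sum(y_true == 0 & y_pred == 1)
  ), class = "ac4c_confusion")
}

#' @export
print.ac4c_confusion <- function(x, ...) {
  cat(sprintf("confusion: N+=%d N-=%d  FN=%d FP=%d (TP=%d TN=%d)\n",
              x$n_pos, x$n_neg, x$fn, x$fp, x$n_pos - x$fn, x$n_neg - x$fp))
  invisible(x)
}

#' Accuracy from confusion counts
#'
#' ACC = 1 - (FN + FP) / (N+ + N-).
#' @param cc An `ac4c_confusion` object.
#' @return Numeric in \[0, 1\].
#' @export
accuracy <- function(cc) {
  1 - (cc$fn + cc$fp) / (cc$n_pos + cc$n_neg)
}

#' Sensitivity (recall on the ac4C class)
#'
#' SN = 1 - FN / N+. Undefined when no positives are present.
#' @inheritParams accuracy
#' @return Numeric in \[0, 1\].
#' @export
sensitivity <- function(cc) {
  if (cc$n_pos == 0L) abort_undefined_metric("sensitivity undefined: no positive examples")
  1 - cc$fn / cc$n_pos
}

#' Specificity (recall on the non-site class)
#'
#' SP = 1 - FP / N-. Undefined when no negatives are present.
#' @inheritParams accuracy
#' @return Numeric in \[0, 1\].
#' @export
specificity <- function(cc) {
  if (cc$n_neg == 0L) abort_undefined_metric("specificity undefined: no negative examples")
  1 - cc$fp / cc$n_neg
}

#' Matthews correlation coefficient (four-count form)
#'
#' MCC in the Chou four-count parameterization,
#' \deqn{\mathrm{MCC} = \frac{1 - (N^+_-/N^+ + N^-_+/N^-)}
#'   {\sqrt{(1 + (FP - FN)/N^+)(1 + (FN - FP)/N^-)}},}
#' which is algebraically identical to the standard
#' (TP·TN - FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) form. Undefined when
#' either class is absent or a prediction column is empty (zero denominator).
#'
#' @inheritParams accuracy
#' @return Numeric in \[-1, 1\].
#' @export
mcc <- function(cc) {
  if (cc$n_pos == 0L || cc$n_neg == 0L)
    abort_undefined_metric("MCC undefined: one class absent")
  num <- 1 - (cc$fn / cc$n_pos + cc$fp / cc$n_neg)
  den2 <- (1 + (cc$fp - cc$fn) / cc$n_pos) * (1 + (cc$fn - cc$fp) / cc$n_neg)
  if (den2 <= 0)
    abort_undefined_metric("MCC undefined: degenerate prediction column (zero denominator)")
  num / sqrt(den2)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic (fraction of positive-negative
#' pairs ranked correctly, ties counted one half), which equals trapezoidal
#' integration of the ROC curve with tied scores grouped at one threshold.
#'
#' @param y_true Binary 0/1 labels.
#' @param scores Real-valued scores, higher = more ac4C-like.
#' @return Numeric in \[0, 1\].
#' @export
auroc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    abort_validation("y_true and scores must have equal length")
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0L || n0 == 0L)
    abort_undefined_metric("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step summation (average-precision style): thresholds
#' sweep the distinct score values in decreasing order, tied scores enter as
#' one block, and each block contributes (delta recall) x (precision at the
#' threshold). Linear PR interpolation is deliberately avoided — it inflates
#' areas on imbalanced data, and the 1:9 site/non-site imbalance is the whole
#' point of this metric here.
#'
#' @inheritParams auroc
#' @return Numeric in (0, 1\].
#' @export
auprc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    abort_validation("y_true and scores must have equal length")
  n1 <- sum(y_true == 1)
  if (n1 == 0L || all(y_true == 1))
    abort_undefined_metric("AUPRC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  block_last <- cumsum(rle(s)$lengths)      # indices ending each tie block
  tp <- cumsum(y)[block_last]
  n_called <- block_last
  precision <- tp / n_called
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Stratified k-fold assignment
#'
#' Within each class, indices are shuffled by `seed` and dealt round-robin
#' into `k` folds, so per-fold class counts differ from perfect
#' stratification by at most one. Fold ids are 1-based (1..k).
#'
#' @param labels Binary 0/1 vector.
#' @param k Number of folds (default 5).
#' @param seed Integer RNG seed.
#' @return An `ac4c_folds` object: integer fold id per index, with `k` and
#'   `seed` attributes.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 42L) {
  if (!all(labels %in% c(0, 1)))
    abort_validation("labels must be binary 0/1")
  for (cl in c(0, 1)) {
    if (sum(labels == cl) < k)
      abort_validation(sprintf("class %d has fewer than k = %d members", cl, k))
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(fold, k = as.integer(k), seed = as.integer(seed),
            class = "ac4c_folds")
}

# run `expr` under a fixed, named RNG so results are portable, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  eval.parent(substitute(expr))
}

#' All six benchmark metrics from labels and scores
#'
#' ACC/SN/SP/MCC at the probability threshold, plus AUROC and AUPRC. A label
#' metric that is undefined for the thresholded predictions (e.g. MCC when
#' the classifier calls every example one class) is reported as `NA` rather
#' than aborting — the threshold-free metrics remain informative in that
#' situation. AUROC/AUPRC still signal when a class is absent from
#' `y_true`.
#'
#' @inheritParams auroc
#' @param threshold Probability cutoff for the label metrics (default 0.5).
#' @return Named numeric vector (acc, sn, sp, mcc, auroc, auprc).
#' @export
score_predictions <- function(y_true, scores, threshold = 0.5) {
  cc <- confusion_counts(y_true, as.integer(scores >= threshold))
  na_if_undefined <- function(expr) {
    tryCatch(expr, ac4c_undefined_metric = function(e) NA_real_)
  }
  c(acc = accuracy(cc),
    sn = na_if_undefined(sensitivity(cc)),
    sp = na_if_undefined(specificity(cc)),
    mcc = na_if_undefined(mcc(cc)),
    auroc = auroc(y_true, scores),
    auprc = auprc(y_true, scores))
}

#' Stratified k-fold cross-validation of the site classifier
#'
#' For each fold the classifier is trained on the remaining k-1 folds and
#' scored on the held-out fold; the reported performance is the arithmetic
#' mean over folds.
#'
#' @param x Feature matrix (rows = sequences) or named character vector of
#'   sequences (encoded with `scheme`).
#' @param y Binary 0/1 labels aligned with `x` rows.
#' @param config An [ac4c_config()]; ignored when `fit_fun` is given.
#' @param k Number of folds.
#' @param seed Integer seed controlling the fold shuffle and model training.
#' @param scheme Encoding scheme used when `x` holds raw sequences.
#' @param threshold Probability cutoff for the label metrics.
#' @param fit_fun Optional `function(X, y, seed)` returning an object whose
#'   `predict_proba()` yields scores — used for baseline classifiers.
#' @return An `ac4c_cv` object: `per_fold` data frame (k rows, six metric
#'   columns; label metrics undefined on a fold appear as `NA`), `mean`
#'   (named numeric, averaged over defined folds), `folds`, `k`, `seed`,
#'   `threshold`.
#' @export
cross_validate <- function(x, y, config = ac4c_config(), k = 5L, seed = 42L,
                           scheme = "eiip_pseeiip", threshold = 0.5,
                           fit_fun = NULL) {
  X <- if (is.character(x)) encode_dataset(x, scheme) else x
  if (nrow(X) != length(y))
    abort_validation("x rows and y must be aligned")
  folds <- stratified_kfold(y, k = k, seed = seed)
  per_fold <- matrix(NA_real_, nrow = k, ncol = 6,
                     dimnames = list(NULL, c("acc", "sn", "sp", "mcc", "auroc", "auprc")))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[te])) < 2L)
      abort_undefined_metric(sprintf("fold %d holds a single class", f))
    scorer <- if (is.null(fit_fun)) {
      cfg <- config; cfg$seed <- config$seed + f - 1L
      ac4c_fit(X[tr, , drop = FALSE], y[tr], config = cfg)
    } else {
      fit_fun(X[tr, , drop = FALSE], y[tr], seed + f - 1L)
    }
    scores <- predict_proba(scorer, X[te, , drop = FALSE])
    per_fold[f, ] <- score_predictions(y[te], scores, threshold)
  }
  structure(list(
    per_fold = as.data.frame(per_fold),
    mean = colMeans(per_fold, na.rm = TRUE),
    folds = folds, k = as.integer(k), seed = as.integer(seed),
    threshold = threshold
  ), class = "ac4c_cv")
}

#' @export
print.ac4c_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %d, threshold %.2f)\n",
              x$k, x$seed, x$threshold))
  tab <- rbind(round(x$per_fold, digits), round(x$mean, digits))
  rownames(tab) <- c(sprintf("fold %d", seq_len(x$k)), "mean")
  print(tab)
  invisible(x)
}

#' Serialize a cross-validation report to JSON
#'
#' @param cv An `ac4c_cv` object.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
cv_to_json <- function(cv, path = NULL) {
  obj <- list(k = cv$k, seed = cv$seed, threshold = cv$threshold,
              per_fold = cv$per_fold, mean = as.list(cv$mean))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
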