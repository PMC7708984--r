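# Per-feature attribution for the boosted-tree classifier.
#
# Global attributions are exact Shapley values for tree ensembles (TreeSHAP),
# computed from the booster's structure on the margin (log-odds) scale — the
# additive scale of the model, on which local accuracy holds exactly. The
# local explainer is a surrogate-model recipe: quartile discretization of the
# feature space, seeded perturbations around the instance, and a
# distance-kernel-weighted ridge fit whose signed weights indicate support
# for (positive) or against (negative) an ac4C call.

#' Global Shapley attribution report
#'
#' Computes per-sample Shapley attributions for every feature from the tree
#' ensemble's structure, ranks features by mean absolute attribution, and
#' retains the `top_k` with their attribution/feature-value sign
#' relationship (the correlation between a feature's value and its
#' attribution across samples, positive when high values push toward the
#' site class).
#'
#' @param model An `ac4c_model`.
#' @param X Feature matrix compatible with the model.
#' @param top_k Number of top-ranked features to report (default 20).
#' @return An `ac4c_attribution` object: `top` data frame (feature,
#'   mean_abs_attribution, value_sign_correlation), `global_importance`
#'   (full named vector, descending), `per_sample` attribution matrix,
#'   `base_value`, and `scale = "margin"`.
#' @export
global_attribution <- function(model, X, top_k = 20L) {
  check_compatible(model, X)
  Xm <- unname(as.matrix(X))
  contrib <- stats::predict(model_booster(model), Xm, predcontrib = TRUE)
  p <- length(model$feature_names)
  base_value <- contrib[, p + 1L][1]
  phi <- contrib[, seq_len(p), drop = FALSE]
  colnames(phi) <- model$feature_names
  imp <- colMeans(abs(phi))
  ord <- order(imp, decreasing = TRUE)
  top_k <- min(top_k, p)
  sel <- ord[seq_len(top_k)]
  sign_cor <- vapply(sel, function(j) {
    if (stats::sd(Xm[, j]) == 0 || stats::sd(phi[, j]) == 0) return(0)
    stats::cor(Xm[, j], phi[, j])
  }, numeric(1))
  structure(list(
    top = data.frame(feature = model$feature_names[sel],
                     mean_abs_attribution = unname(imp[sel]),
                     value_sign_correlation = sign_cor),
    global_importance = imp[ord],
    per_sample = phi,
    base_value = base_value,
    scale = "margin",
    top_k = as.integer(top_k)
  ), class = "ac4c_attribution")
}

#' @export
print.ac4c_attribution <- function(x, ...) {
  cat(sprintf("Shapley attribution report (margin scale), top %d of %d features:\n",
              x$top_k, length(x$global_importance)))
  print(transform(x$top,
                  mean_abs_attribution = signif(mean_abs_attribution, 4),
                  value_sign_correlation = signif(value_sign_correlation, 3)))
  invisible(x)
}

#' Beeswarm-style summary plot of the attribution report
#'
#' Horizontal scatter of per-sample attributions for the top features,
#' shaded by feature value (low = blue, high = red).
#'
#' @param x An `ac4c_attribution` object.
#' @param X The feature matrix the report was computed on.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.ac4c_attribution <- function(x, X = NULL, ...) {
  feats <- rev(x$top$feature)
  k <- length(feats)
  op <- graphics::par(mar = c(4, 8, 2, 1)); on.exit(graphics::par(op))
  rng <- range(x$per_sample[, feats])
  graphics::plot(NA, xlim = rng, ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "Shapley attribution (margin scale)", ylab = "",
                 main = sprintf("top %d features", k))
  graphics::axis(2, at = seq_len(k), labels = feats, las = 1, cex.axis = 0.7)
  for (i in seq_len(k)) {
    v <- x$per_sample[, feats[i]]
    col <- "grey40"
    if (!is.null(X)) {
      fv <- X[, feats[i]]
      z <- if (stats::sd(fv) > 0) (fv - min(fv)) / diff(range(fv)) else rep(0.5, length(fv))
      col <- grDevices::rgb(z, 0.2, 1 - z, alpha = 0.5)
    }
    graphics::points(v, i + stats::runif(length(v), -0.25, 0.25), pch = 16,
                     cex = 0.4, col = col)
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

# bin edges per feature from the model's stored training quartiles
feature_bins <- function(model, j) {
  q <- model$feature_quartiles[j, ]   # min, q1, median, q3, max
  unique(q)
}

bin_of <- function(value, edges) {
  # edges include min and max; bins are [e1,e2], (e2,e3], ...
  b <- findInterval(value, edges, rightmost.closed = TRUE, left.open = TRUE)
  max(1L, min(b + ifelse(value <= edges[1], 1L, 0L), length(edges) - 1L))
}

bin_label <- function(name, edges, b) {
  if (length(edges) <= 2L || b + 1L > length(edges))
    return(sprintf("%s = %s", name, signif(edges[min(b, length(edges))], 4)))
  sprintf("%s in (%s, %s]", name, signif(edges[b], 4), signif(edges[b + 1L], 4))
}

#' Local surrogate explanation of one prediction
#'
#' Explains a single scored window by fitting an interpretable surrogate
#' around it: each feature is discretized into training-set quartile bins;
#' perturbed samples redraw each feature's bin uniformly (value drawn
#' uniformly within the bin); samples are weighted by an exponential kernel
#' on the Hamming distance between their bin pattern and the instance's; and
#' a weighted ridge regression of the model's predicted probability on the
#' same-bin indicators yields one signed weight per feature. A positive
#' weight means "this feature sitting in its current value range supports
#' the ac4C call"; negative opposes it.
#'
#' @param model An `ac4c_model` (its stored training quartiles define the
#'   bins).
#' @param x A single feature row (numeric vector or 1-row matrix) compatible
#'   with the model.
#' @param num_features Number of top-|weight| features to return.
#' @param n_samples Number of seeded perturbations (default 5000).
#' @param seed Integer seed; identical seeds give identical explanations.
#' @param kernel_width Kernel width for the distance weighting; default
#'   `0.75 * sqrt(p)`.
#' @return An `ac4c_local_explanation`: data frame `weights` (feature,
#'   weight, range), `predicted_probability`, `intercept`, `seed`.
#' @export
local_explanation <- function(model, x, num_features = 10L, n_samples = 5000L,
                              seed = 42L, kernel_width = NULL) {
  x <- as.numeric(x)
  p <- length(model$feature_names)
  if (length(x) != p)
    abort_validation(sprintf("row width %d does not match the model's %d features",
                             length(x), p))
  num_features <- min(num_features, p)
  edges <- lapply(seq_len(p), function(j) feature_bins(model, j))
  x_bin <- vapply(seq_len(p), function(j) bin_of(x[j], edges[[j]]), integer(1))
  n_bins <- vapply(edges, function(e) length(e) - 1L, integer(1))
  n_bins[n_bins < 1L] <- 1L
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(p)

  with_seed(seed, {
    # sampled bin per feature per perturbation; first sample is the instance
    Z <- matrix(0L, nrow = n_samples, ncol = p)
    V <- matrix(0, nrow = n_samples, ncol = p)
    for (j in seq_len(p)) {
      e <- edges[[j]]
      if (length(e) == 1L) {            # constant feature: nothing to perturb
        V[, j] <- e[1]
        Z[, j] <- 1L
        next
      }
      b <- sample.int(n_bins[j], n_samples, replace = TRUE)
      b[1] <- x_bin[j]
      lo <- e[b]; hi <- e[b + 1L]
      V[, j] <- stats::runif(n_samples, lo, hi)
      V[1, j] <- x[j]
      Z[, j] <- as.integer(b == x_bin[j])
    }
    scores <- predict_proba(model, V)
    d2 <- rowSums((Z - 1L)^2)           # Hamming distance to the instance
    w <- exp(-d2 / kernel_width^2)
    # weighted ridge: (Z'WZ + lambda I) beta = Z'W y
    Zc <- cbind(1, Z)
    A <- crossprod(Zc * w, Zc)
    diag(A)[-1] <- diag(A)[-1] + 1e-3
    beta <- solve(A, crossprod(Zc * w, scores))
  })
  weights <- beta[-1]
  sel <- order(abs(weights), decreasing = TRUE)[seq_len(num_features)]
  ranges <- vapply(sel, function(j) bin_label(model$feature_names[j],
                                              edges[[j]], x_bin[j]), character(1))
  structure(list(
    weights = data.frame(feature = model$feature_names[sel],
                         weight = as.numeric(weights[sel]),
                         range = ranges),
    predicted_probability = unname(predict_proba(model, matrix(x, nrow = 1))),
    intercept = as.numeric(beta[1]),
    seed = as.integer(seed),
    n_samples = as.integer(n_samples)
  ), class = "ac4c_local_explanation")
}

#' @export
print.ac4c_local_explanation <- function(x, ...) {
  cat(sprintf("local surrogate explanation (p(ac4C) = %.3f, %d perturbations, seed %d)\n",
              x$predicted_probability, x$n_samples, x$seed))
  df <- x$weights
  df$weight <- signif(df$weight, 4)
  df$direction <- ifelse(df$weight >= 0, "supports ac4C", "opposes ac4C")
  print(df)
  invisible(x)
}

#' Bar chart of a local explanation
#'
#' Green bars support the ac4C call, red bars oppose it.
#' @param x An `ac4c_local_explanation`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.ac4c_local_explanation <- function(x, ...) {
  df <- x$weights[order(abs(x$weights$weight)), ]
  op <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(df$weight, names.arg = df$range, horiz = TRUE, las = 1,
                    col = ifelse(df$weight >= 0, "forestgreen", "firebrick"),
                    cex.names = 0.7, xlab = "surrogate weight",
                    main = sprintf("p(ac4C) = %.3f", x$predicted_probability))
  graphics::abline(v = 0)
  invisible(x)
}

#' Serialize an attribution report to JSON
#'
#' @param report An `ac4c_attribution` or `ac4c_local_explanation`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
attribution_to_json <- function(report, path = NULL) {
  obj <- if (inherits(report, "ac4c_attribution")) {
    list(scale = report$scale, base_value = report$base_value, top = report$top)
  } else {
    list(predicted_probability = report$predicted_probability,
         seed = report$seed, weights = report$weights)
  }
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
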