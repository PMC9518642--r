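# Linear color-harmony modeling: min-max feature normalization, the bundled
# fitted regression model, OLS fitting with optional greedy backward
# elimination, threshold classification, k-fold cross-validated evaluation,
# rater reliability (Cronbach's alpha), and the pleasure-arousal map.

# ---------------------------------------------------------------------------
# normalization --------------------------------------------------------------

#' Fit min-max normalization parameters
#'
#' Records the per-feature minimum and maximum over a reference dataset,
#' for the rescaling `x' = (x - min) / (max - min)`.
#'
#' @param features Numeric matrix or data frame, one column per feature
#'   (named columns).
#' @return An object of class `norm_params` with fields `min` and `max`.
#' @export
fit_norm_params <- function(features) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  structure(list(min = apply(X, 2L, min), max = apply(X, 2L, max)),
            class = "norm_params")
}

#' Min-max normalize features
#'
#' Applies `(x - min) / (max - min)` per feature. Values falling outside
#' `[0, 1]` at inference (new data beyond the fitted range) are clamped
#' with a warning; features that were constant in the fitting set map
#' to 0.
#'
#' @param features Numeric matrix/data frame or named numeric vector.
#' @param norm A `norm_params` object from [fit_norm_params()].
#' @return Normalized features, same shape, values in `[0, 1]`.
#' @export
normalize_features <- function(features, norm) {
  if (!inherits(norm, "norm_params")) stop("norm must be fitted norm_params")
  vec <- is.null(dim(features))
  X <- if (vec) matrix(features, nrow = 1L, dimnames = list(NULL, names(features)))
       else as.matrix(features)
  miss <- setdiff(colnames(X), names(norm$min))
  if (length(miss)) stop("norm_params missing features: ", paste(miss, collapse = ", "))
  lo <- norm$min[colnames(X)]; hi <- norm$max[colnames(X)]
  rng <- hi - lo
  out <- sweep(sweep(X, 2L, lo), 2L, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  if (any(out < -1e-9) || any(out > 1 + 1e-9))
    warning("normalize_features: values outside the fitted range clamped to [0, 1]")
  out <- pmin(pmax(out, 0), 1)
  if (vec) stats::setNames(out[1L, ], colnames(X)) else out
}

# ---------------------------------------------------------------------------
# model container ------------------------------------------------------------

#' Linear color-harmony model container
#'
#' An intercept plus per-feature coefficients over a (possibly strict)
#' subset of the 16 features; features absent from `coefficients` are
#' excluded from the model. `norm` optionally bundles the min-max
#' parameters the model expects its inputs to be scaled with (`NULL`
#' means inputs are already normalized).
#'
#' @param intercept Scalar intercept.
#' @param coefficients Named numeric vector of slopes.
#' @param norm Optional [fit_norm_params()] output.
#' @param threshold Classification threshold (default 0).
#' @return An object of class `harmony_model`.
#' @export
harmony_model <- function(intercept, coefficients, norm = NULL, threshold = 0) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("intercept must be a finite scalar")
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be named by feature")
  if (!all(is.finite(coefficients))) stop("coefficients must be finite")
  if (!is.null(norm) && !inherits(norm, "norm_params"))
    stop("norm must be NULL or norm_params")
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 norm = norm,
                 threshold = threshold),
            class = "harmony_model")
}

#' @export
print.harmony_model <- function(x, ...) {
  cat("<harmony_model>\n")
  cat("  score =", format(x$intercept), "+",
      paste(sprintf("%s*%s", format(unname(x$coefficients)), names(x$coefficients)),
            collapse = " + "), "\n")
  cat("  threshold:", x$threshold,
      if (is.null(x$norm)) "(inputs taken as already normalized)" else "(min-max norm bundled)", "\n")
  invisible(x)
}

#' The bundled reference color-harmony model
#'
#' The fitted multiple-linear-regression model for the harmony of
#' multi-color film-scene materials, over seven min-max normalized
#' features:
#' `score = 1.499 f1 + 0.408 f4 - 0.594 f5 - 0.52 f11 - 0.47 f13
#'  - 1.386 f14 + 0.862 f15 + 0.249`.
#' The normalization bounds of the original training set are not
#' published, so the model ships without `norm`: inputs must already be
#' min-max normalized (the CLI refuses to score raw features unless
#' normalization parameters are supplied or computed from the batch).
#'
#' @param norm Optional [fit_norm_params()] output to bundle.
#' @return A [harmony_model()].
#' @export
reference_harmony_model <- function(norm = NULL) {
  harmony_model(
    intercept = 0.249,
    coefficients = c(f1 = 1.499, f4 = 0.408, f5 = -0.594, f11 = -0.52,
                     f13 = -0.47, f14 = -1.386, f15 = 0.862),
    norm = norm,
    threshold = 0
  )
}

#' Predict harmony scores
#'
#' `intercept + sum(coef * feature)` over the model's feature subset. If
#' the model bundles normalization parameters the features are first
#' min-max rescaled with them; otherwise they are used as-is (and must
#' already be normalized for the reference model).
#'
#' @param model A [harmony_model()].
#' @param features Named numeric vector, matrix or data frame containing
#'   at least the model's features.
#' @return Numeric vector of harmony scores.
#' @export
predict_harmony <- function(model, features) {
  if (!inherits(model, "harmony_model")) stop("model must be a harmony_model")
  vec <- is.null(dim(features))
  X <- if (vec) matrix(features, nrow = 1L, dimnames = list(NULL, names(features)))
       else as.matrix(features)
  need <- names(model$coefficients)
  miss <- setdiff(need, colnames(X))
  if (length(miss))
    stop("missing required feature(s): ", paste(miss, collapse = ", "))
  if (!is.null(model$norm)) X <- normalize_features(X, model$norm)
  drop(model$intercept + X[, need, drop = FALSE] %*% model$coefficients[need])
}

#' Map pleasure/arousal coordinates to a harmony score
#'
#' Linear bridge from the pleasure (P) and arousal (A) axes of the PAD
#' emotion space to color harmony: `CH = 0.813 P - 0.616 A + 0.374`.
#'
#' @param P,A Numeric vectors of pleasure and arousal values.
#' @return Numeric vector of harmony scores.
#' @export
pad_to_harmony <- function(P, A) {
  if (!all(is.finite(P)) || !all(is.finite(A))) stop("P and A must be finite")
  0.813 * P - 0.616 * A + 0.374
}

# ---------------------------------------------------------------------------
# fitting --------------------------------------------------------------------

#' Fit a linear harmony model by ordinary least squares
#'
#' Minimizes the residual sum of squares with an intercept. Rank-deficient
#' design matrices are rejected unless `ridge = TRUE`, in which case a
#' small-ridge fallback is used with a warning. Optional greedy backward
#' elimination drops, one at a time, the feature whose removal most
#' improves cross-validated RMSE (a plain stand-in for rule-based
#' attribute selection).
#'
#' @param features Numeric matrix/data frame of predictors (named columns).
#' @param targets Numeric response vector.
#' @param norm Optional [fit_norm_params()] to bundle with the model (the
#'   features are then normalized before fitting).
#' @param backward_eliminate Run greedy backward elimination (default FALSE).
#' @param cv_k,cv_seed Folds and seed for the elimination criterion.
#' @param ridge Enable the ridge fallback for rank-deficient designs.
#' @param threshold Classification threshold stored in the model.
#' @return A [harmony_model()].
#' @export
fit_ols <- function(features, targets, norm = NULL, backward_eliminate = FALSE,
                    cv_k = 10L, cv_seed = 0L, ridge = FALSE, threshold = 0) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(targets)
  if (nrow(X) != length(y)) stop("features/targets length mismatch")
  if (nrow(X) < ncol(X) + 1L) stop("need at least as many rows as coefficients")
  if (!is.null(norm)) X <- normalize_features(X, norm)

  solve_ols <- function(Xs, ys) {
    D <- cbind(`(Intercept)` = 1, Xs)
    qr_d <- qr(D)
    if (qr_d$rank < ncol(D)) {
      if (!ridge) stop("design matrix is rank deficient; enable ridge = TRUE for a regularized fallback")
      warning("rank-deficient design: using ridge fallback (lambda = 1e-8)")
      beta <- solve(crossprod(D) + diag(1e-8, ncol(D)), crossprod(D, ys))
      return(drop(beta))
    }
    qr.coef(qr_d, ys)
  }

  cols <- colnames(X)
  if (backward_eliminate && length(cols) > 1L) {
    score_subset <- function(sub) {
      rep_ <- kfold_cv(X[, sub, drop = FALSE], y, k = cv_k, seed = cv_seed)
      rep_$rmse
    }
    cur <- score_subset(cols)
    repeat {
      if (length(cols) == 1L) break
      trials <- vapply(cols, function(dropped) score_subset(setdiff(cols, dropped)),
                       numeric(1))
      best <- which.min(trials)
      if (trials[best] <= cur) {
        cur <- trials[best]
        cols <- setdiff(cols, cols[best])
      } else break
    }
  }

  beta <- solve_ols(X[, cols, drop = FALSE], y)
  harmony_model(intercept = beta[1L],
                coefficients = stats::setNames(beta[-1L], cols),
                norm = norm, threshold = threshold)
}

#' Classify harmony scores at a threshold
#'
#' A material is "harmonious" when its predicted score is strictly greater
#' than the threshold `T`, "disharmonious" otherwise (a score exactly at
#' the threshold is disharmonious).
#'
#' @param model A [harmony_model()] (or `NULL` to classify raw scores).
#' @param features Features accepted by [predict_harmony()], or, when
#'   `model` is `NULL`, a numeric vector of scores.
#' @param threshold Overrides the model threshold (default: the model's).
#' @return Character vector of `"harmonious"` / `"disharmonious"`.
#' @export
classify_harmony <- function(model, features, threshold = NULL) {
  if (is.null(model)) {
    scores <- as.numeric(features)
    T_ <- if (is.null(threshold)) 0 else threshold
  } else {
    scores <- predict_harmony(model, features)
    T_ <- if (is.null(threshold)) model$threshold else threshold
  }
  ifelse(scores > T_, "harmonious", "disharmonious")
}

# ---------------------------------------------------------------------------
# evaluation -----------------------------------------------------------------

#' Mean absolute error
#' @param pred,truth Equal-length numeric vectors.
#' @return `mean(|truth - pred|)`.
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 1L) stop("need n >= 1")
  mean(abs(truth - pred))
}

#' Root mean squared error
#' @param pred,truth Equal-length numeric vectors.
#' @return `sqrt(mean((truth - pred)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 1L) stop("need n >= 1")
  sqrt(mean((truth - pred)^2))
}

#' Correct classification rate
#'
#' Overall binary accuracy `(TP + TN) / (P + N)`.
#'
#' @param pred,truth Equal-length label vectors (any comparable type).
#' @return Accuracy in `[0, 1]`.
#' @export
correct_classification_rate <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 1L) stop("need n >= 1")
  mean(pred == truth)
}

#' Pearson correlation with significance
#'
#' Sample Pearson correlation coefficient together with the two-sided
#' p-value of the usual t test.
#'
#' @param x,y Numeric vectors, `n >= 3`, neither constant.
#' @return List with `r` and `p_value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  if (.pop_var(x) == 0 || .pop_var(y) == 0) stop("constant input vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' k-fold cross-validated model evaluation
#'
#' Shuffles the data under a fixed seed, splits into `k` folds (stratified
#' by class for the classification task), fits an OLS model on each
#' training complement and evaluates on the held-out fold. Predictions
#' are pooled across folds before computing the summary statistics.
#'
#' For `task = "classification"` the numeric targets are thresholded at
#' `threshold` to obtain the true labels, the regression predictions are
#' thresholded the same way, and the correct classification rate is
#' reported alongside MAE/RMSE of the underlying scores.
#'
#' @param features Predictor matrix/data frame.
#' @param targets Numeric response vector.
#' @param k Number of folds (default 10).
#' @param seed Shuffle seed (default 0).
#' @param task `"regression"` or `"classification"`.
#' @param threshold Class threshold for the classification task (default 0).
#' @return List of class `eval_report`: `task`, `k`, pooled `pearson_r`,
#'   `mae`, `rmse` (and `cc` for classification), and a `folds` data frame.
#' @export
kfold_cv <- function(features, targets, k = 10L, seed = 0L,
                     task = c("regression", "classification"), threshold = 0) {
  task <- match.arg(task)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(targets)
  n <- length(y)
  k <- as.integer(k)
  if (k > n) stop("k must not exceed the number of observations")
  if (k < 2L) stop("k must be >= 2")

  fold_of <- integer(n)
  .with_seed(seed, {
    if (task == "classification") {
      cls <- y > threshold
      for (g in unique(cls)) {
        idx <- sample(which(cls == g))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold_of[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })

  pred <- numeric(n)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold_of == f
    fit <- fit_ols(X[!test, , drop = FALSE], y[!test])
    pred[test] <- predict_harmony(fit, X[test, , drop = FALSE])
    fold_rows[[f]] <- data.frame(fold = f, n = sum(test),
                                 mae = mae(pred[test], y[test]),
                                 rmse = rmse(pred[test], y[test]))
  }

  out <- list(task = task, k = k,
              mae = mae(pred, y), rmse = rmse(pred, y),
              pearson_r = if (.pop_var(pred) > 0 && .pop_var(y) > 0)
                pearson_r(pred, y)$r else NA_real_,
              folds = do.call(rbind, fold_rows),
              predictions = pred)
  if (task == "classification") {
    out$cc <- correct_classification_rate(pred > threshold, y > threshold)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d-fold %s>\n", x$k, x$task))
  cat(sprintf("  pooled: r = %.4f, MAE = %.4f, RMSE = %.4f%s\n",
              x$pearson_r, x$mae, x$rmse,
              if (!is.null(x$cc)) sprintf(", CC = %.4f", x$cc) else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# reliability ----------------------------------------------------------------

#' Cronbach's alpha inter-rater reliability
#'
#' Internal consistency of a materials-by-raters score matrix:
#' `alpha = K/(K-1) * (1 - sum_i var(Y_i) / var(X))`, where `K` is the
#' number of raters, `var(Y_i)` the population variance of rater `i`'s
#' scores across materials, and `var(X)` the population variance of the
#' per-material total scores.
#'
#' @param ratings Numeric matrix with materials in rows and raters in
#'   columns (flip with `raters`). No missing cells.
#' @param raters `"columns"` (default) or `"rows"`: which margin holds
#'   the raters.
#' @return Alpha (at most 1; can be negative for inconsistent raters).
#' @export
cronbach_alpha <- function(ratings, raters = c("columns", "rows")) {
  raters <- match.arg(raters)
  x <- as.matrix(ratings)
  if (raters == "rows") x <- t(x)
  if (anyNA(x)) stop("ratings must have no missing cells")
  K <- ncol(x)
  if (K < 2L) stop("need at least 2 raters")
  if (nrow(x) < 2L) stop("need at least 2 materials")
  var_raters <- apply(x, 2L, .pop_var)
  var_total <- .pop_var(rowSums(x))
  if (var_total == 0) stop("total scores are constant; alpha undefined")
  K / (K - 1) * (1 - sum(var_raters) / var_total)
}

# ---------------------------------------------------------------------------
# persistence ----------------------------------------------------------------

#' Write a harmony model to JSON
#'
#' Human-diffable persistence: fields `intercept`, `coefficients` (keyed
#' by feature name), `threshold` and optionally `norm` (`min`/`max` per
#' feature).
#'
#' @param model A [harmony_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_harmony_model <- function(model, path) {
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              threshold = model$threshold)
  if (!is.null(model$norm))
    obj$norm <- list(min = as.list(model$norm$min), max = as.list(model$norm$max))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a harmony model from JSON
#'
#' @param path File written by [write_harmony_model()].
#' @return A [harmony_model()].
#' @export
read_harmony_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- NULL
  if (!is.null(obj$norm))
    norm <- structure(list(min = unlist(obj$norm$min), max = unlist(obj$norm$max)),
                      class = "norm_params")
  harmony_model(intercept = obj$intercept,
                coefficients = unlist(obj$coefficients),
                norm = norm,
                threshold = if (is.null(obj$threshold)) 0 else obj$threshold)
}
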