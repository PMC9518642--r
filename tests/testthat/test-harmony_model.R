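# Normalization, the bundled linear model, OLS fitting, classification,
# cross-validation, error statistics, reliability, correlation.

ref_zero <- function() {
  m <- reference_harmony_model()
  stats::setNames(rep(0, length(m$coefficients)), names(m$coefficients))
}

test_that("min-max normalization maps the fitted range onto [0, 1]", {
  X <- cbind(f1 = c(2, 4, 6), f2 = c(-1, 0, 3), f3 = c(5, 5, 5))
  np <- fit_norm_params(X)
  Z <- normalize_features(X, np)
  expect_equal(Z[, "f1"], c(0, 0.5, 1))
  expect_equal(Z[, "f2"], c(0, 0.25, 1))
  expect_equal(Z[, "f3"], c(0, 0, 0))      # constant feature maps to 0
  expect_true(all(Z >= 0 & Z <= 1))
  expect_warning(normalize_features(cbind(f1 = 10, f2 = 0, f3 = 5), np),
                 "clamped")
  expect_error(normalize_features(cbind(f9 = 1), np), "missing")
  expect_error(normalize_features(X, list(min = 0)), "norm_params")
})

test_that("the bundled model carries the printed coefficients exactly", {
  m <- reference_harmony_model()
  expect_identical(m$intercept, 0.249)
  expect_identical(m$coefficients,
                   c(f1 = 1.499, f4 = 0.408, f5 = -0.594, f11 = -0.52,
                     f13 = -0.47, f14 = -1.386, f15 = 0.862))
  expect_identical(m$threshold, 0)
})

test_that("predict_harmony is the stated affine form", {
  m <- reference_harmony_model()
  z <- ref_zero()
  expect_equal(predict_harmony(m, z), 0.249)
  z1 <- z; z1["f1"] <- 1
  expect_equal(predict_harmony(m, z1), 0.249 + 1.499)
  expect_error(predict_harmony(m, c(f1 = 0.5)), "f4")

  flat <- harmony_model(0.7, c(f1 = 0, f2 = 0))
  expect_equal(predict_harmony(flat, cbind(f1 = runif(5), f2 = runif(5))),
               rep(0.7, 5))

  # affine in the features: prediction of a convex combination equals the
  # combination of predictions
  a <- stats::setNames(runif(7), names(m$coefficients))
  b <- stats::setNames(runif(7), names(m$coefficients))
  for (w in c(0.2, 0.5, 0.9)) {
    expect_equal(predict_harmony(m, w * a + (1 - w) * b),
                 w * predict_harmony(m, a) + (1 - w) * predict_harmony(m, b),
                 tolerance = 1e-12)
  }
})

test_that("pad_to_harmony is the printed linear map", {
  expect_equal(pad_to_harmony(0, 0), 0.374)
  expect_equal(pad_to_harmony(1, 0), 0.813 + 0.374)
  expect_equal(pad_to_harmony(0, 1), -0.616 + 0.374)
  P <- runif(4, -2, 2); A <- runif(4, -2, 2)
  expect_equal(pad_to_harmony(2 * P, 2 * A) - 0.374,
               2 * (pad_to_harmony(P, A) - 0.374), tolerance = 1e-12)
  expect_error(pad_to_harmony(NA, 0), "finite")
})

test_that("OLS interpolates a noiseless linear target exactly", {
  ds <- make_feature_dataset(60, noise_sd = 0, seed = 3, all_features = FALSE)
  fit <- fit_ols(ds$features, ds$targets)
  ref <- reference_harmony_model()
  expect_equal(fit$intercept, ref$intercept, tolerance = 1e-8)
  expect_equal(fit$coefficients[names(ref$coefficients)], ref$coefficients,
               tolerance = 1e-8)
})

test_that("OLS recovers coefficients within 3 standard errors under noise", {
  ds <- make_feature_dataset(500, noise_sd = 0.1, seed = 11, all_features = FALSE)
  fit <- fit_ols(ds$features, ds$targets)
  ref <- reference_harmony_model()
  # classical standard errors from the fitted residuals
  D <- cbind(1, ds$features)
  resid <- ds$targets - predict_harmony(fit, ds$features)
  s2 <- sum(resid^2) / (nrow(D) - ncol(D))
  se <- sqrt(diag(s2 * solve(crossprod(D))))
  est <- c(fit$intercept, fit$coefficients[names(ref$coefficients)])
  truth <- c(ref$intercept, ref$coefficients)
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("OLS residuals are orthogonal to every included feature", {
  ds <- make_feature_dataset(80, noise_sd = 0.3, seed = 21, all_features = FALSE)
  fit <- fit_ols(ds$features, ds$targets)
  resid <- ds$targets - predict_harmony(fit, ds$features)
  expect_lt(max(abs(crossprod(ds$features, resid))), 1e-8)
  expect_lt(abs(sum(resid)), 1e-8)
})

test_that("degenerate designs: constant target and rank deficiency", {
  X <- cbind(f1 = runif(30), f2 = runif(30))
  fit <- fit_ols(X, rep(2.5, 30))
  expect_equal(unname(fit$coefficients), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$intercept, 2.5, tolerance = 1e-10)

  Xd <- cbind(f1 = X[, 1], f2 = 2 * X[, 1])   # collinear
  y <- X[, 1] + rnorm(30, sd = 0.1)
  expect_error(fit_ols(Xd, y), "rank deficient")
  expect_warning(fit2 <- fit_ols(Xd, y, ridge = TRUE), "ridge")
  expect_true(all(is.finite(fit2$coefficients)))
})

test_that("classification uses a strict greater-than threshold", {
  expect_identical(classify_harmony(NULL, c(0.249, -0.1, 0, 1e-12)),
                   c("harmonious", "disharmonious", "disharmonious", "harmonious"))
  m <- reference_harmony_model()
  expect_identical(classify_harmony(m, ref_zero()), "harmonious")
})

test_that("k-fold CV is exact on noiseless data and deterministic", {
  ds <- make_feature_dataset(120, noise_sd = 0, seed = 7, all_features = FALSE)
  rep_ <- kfold_cv(ds$features, ds$targets, k = 10, seed = 1)
  expect_equal(rep_$pearson_r, 1, tolerance = 1e-9)
  expect_equal(rep_$mae, 0, tolerance = 1e-9)
  expect_equal(rep_$rmse, 0, tolerance = 1e-9)
  expect_identical(rep_, kfold_cv(ds$features, ds$targets, k = 10, seed = 1))
  expect_error(kfold_cv(ds$features, ds$targets, k = 121), "exceed")
})

test_that("k-fold CV on permuted targets shows no correlation", {
  ds <- make_feature_dataset(500, noise_sd = 0.1, seed = 13, all_features = FALSE)
  rs <- sapply(1:20, function(s) {
    set.seed(s)
    y <- sample(ds$targets)
    kfold_cv(ds$features, y, k = 10, seed = s)$pearson_r
  })
  # CV-pooled r is negatively biased under the null (each fold's fit chases
  # noise it then mispredicts), so only the positive tail is bounded tightly
  expect_true(all(rs < 0.15))
  expect_lt(mean(abs(rs)), 0.1)
})

test_that("noiseless classification by the generating model is perfect", {
  ds <- make_feature_dataset(200, noise_sd = 0, seed = 17, all_features = FALSE)
  rep_ <- kfold_cv(ds$features, ds$targets, k = 10, seed = 2,
                   task = "classification")
  expect_equal(rep_$cc, 1)
  pred <- classify_harmony(reference_harmony_model(), ds$features)
  truth <- ifelse(ds$targets > 0, "harmonious", "disharmonious")
  expect_equal(correct_classification_rate(pred, truth), 1)
})

test_that("MAE, RMSE and CC behave as defined", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(1, -1), c(0, 0)), 1)
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_equal(mae(c(0, 2), c(0, 0)), 1)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_lte(mae(c(0, 2), c(0, 0)), rmse(c(0, 2), c(0, 0)))
  expect_error(mae(1:3, 1:2), "mismatch")

  expect_equal(correct_classification_rate(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(correct_classification_rate(c(0, 0, 1), c(1, 1, 0)), 0)
  # TP = 3, TN = 2 of P = 4, N = 4
  pred <- c(1, 1, 1, 0, 0, 0, 1, 1)
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(correct_classification_rate(pred, truth), 0.625)
})

test_that("Cronbach's alpha: perfect consistency, shift invariance, noise ordering", {
  truth <- seq(-2, 2, length.out = 20)
  identical_raters <- matrix(rep(truth, 6), 20, 6)
  expect_equal(cronbach_alpha(identical_raters), 1)

  shifted <- identical_raters
  shifted[, 3] <- shifted[, 3] + 5
  expect_equal(cronbach_alpha(shifted), 1)

  alphas <- sapply(c(0.1, 0.5, 1.5, 4), function(sd_) {
    set.seed(40)
    cronbach_alpha(truth + matrix(rnorm(20 * 30, sd = sd_), 20, 30))
  })
  expect_true(all(diff(alphas) < 0))

  expect_equal(cronbach_alpha(t(identical_raters), raters = "rows"), 1)
  expect_error(cronbach_alpha(matrix(1:5, 5, 1)), "2 raters")
})

test_that("pearson_r recovers exact linear relations and rejects constants", {
  x <- runif(20)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 5)$r, -1)
  expect_error(pearson_r(rep(1, 10), runif(10)), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
  r <- pearson_r(1:10, c(2:10, 1))
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

test_that("model JSON persistence round-trips", {
  np <- fit_norm_params(cbind(f1 = c(0, 2), f4 = c(-1, 3)))
  m <- harmony_model(0.5, c(f1 = 1.2, f4 = -0.3), norm = np, threshold = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_harmony_model(m, path)
  m2 <- read_harmony_model(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$threshold, m$threshold)
  expect_equal(unname(m2$norm$min), unname(m$norm$min))
  X <- cbind(f1 = runif(5, 0, 2), f4 = runif(5, -1, 3))
  expect_equal(predict_harmony(m2, X), predict_harmony(m, X))
})
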