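test_that("one latent component fits rank-1 noiseless data exactly", {
  t_ <- withr::with_seed(1, rnorm(12))
  p_ <- c(1, -2, 0.5, 0.1, 3)
  X <- outer(t_, p_)
  y <- 2.5 * t_ + 10
  fit <- fit_plsr(X, y, 1)
  expect_lt(rmse(y, predict_plsr(fit, X)), 1e-8)
  expect_equal(pearson_r(y, predict_plsr(fit, X)), 1, tolerance = 1e-10)
})

test_that("full-component PLSR equals ordinary least squares on full-rank data", {
  X <- withr::with_seed(2, matrix(rnorm(40), 8, 5))
  y <- withr::with_seed(3, rnorm(8))
  fit <- fit_plsr(X, y, 5)
  Xc <- sweep(X, 2, colMeans(X))
  b_ols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_equal(fit$b, as.numeric(b_ols), tolerance = 1e-6)
})

test_that("predictions match an independently coded NIPALS reference", {
  X <- withr::with_seed(4, matrix(rnorm(200), 20, 10))
  y <- withr::with_seed(5, rnorm(20, 10))
  Xnew <- withr::with_seed(6, matrix(rnorm(50), 5, 10))
  fit <- fit_plsr(X, y, 3)
  expect_equal(predict_plsr(fit, Xnew), nipals_reference(X, y, 3, Xnew),
               tolerance = 1e-8)
  # coefficient form agrees with the factor form on training data too
  expect_equal(predict_plsr(fit, X), nipals_reference(X, y, 3, X),
               tolerance = 1e-8)
})

test_that("predictions agree with mixOmics PLS regression", {
  skip_if_not_installed("mixOmics")
  X <- withr::with_seed(7, matrix(rnorm(300), 30, 10,
                                  dimnames = list(NULL, paste0("ch", 1:10))))
  y <- withr::with_seed(8, as.numeric(X %*% rnorm(10) + rnorm(30, sd = 0.1)))
  fit <- fit_plsr(X, y, 4)
  mo <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  pred <- as.numeric(predict(mo, X)$predict[, 1, 4])
  expect_equal(predict_plsr(fit, X), pred, tolerance = 1e-6)
})

test_that("prediction is an affine map centered at the training mean", {
  X <- withr::with_seed(9, matrix(rnorm(100), 10, 10))
  y <- withr::with_seed(10, rnorm(10))
  fit <- fit_plsr(X, y, 3)
  expect_equal(predict_plsr(fit, colMeans(X)), mean(y), tolerance = 1e-10)
  x1 <- X[1, ]; x2 <- X[2, ]; al <- 0.3
  expect_equal(predict_plsr(fit, al * x1 + (1 - al) * x2),
               al * predict_plsr(fit, x1) + (1 - al) * predict_plsr(fit, x2),
               tolerance = 1e-10)
  expect_error(predict_plsr(fit, matrix(0, 1, 4)), "channel count mismatch")
  expect_error(fit_plsr(X, y, 11), "exceeds")
})

test_that("cross-validation recovers a planted two-factor structure", {
  set.seed(11)
  Tm <- matrix(rnorm(80), 40, 2)
  P <- matrix(rnorm(16), 8, 2)
  X <- Tm %*% t(P)
  y <- as.numeric(Tm %*% c(1, -1))
  cv <- cv_plan(40, seed = 1)
  sel <- select_n_components(X, y, 1:6, cv)
  expect_identical(sel$best, 2L)
  expect_lt(sel$rmsecv[["2"]], 1e-6)
  expect_gt(sel$rmsecv[["1"]], 1e-3)
})

test_that("training RMSE is non-increasing in component count and ties pick fewer", {
  X <- withr::with_seed(12, matrix(rnorm(150), 15, 10))
  y <- withr::with_seed(13, rnorm(15))
  rmses <- sapply(1:6, function(a) rmse(y, predict_plsr(fit_plsr(X, y, a), X)))
  expect_true(all(diff(rmses) <= 1e-12))

  # rank-1 X: every component count >= 1 has identical RMSECV -> pick 1
  X1 <- outer(rnorm(20), rnorm(6))
  y1 <- as.numeric(X1[, 1])
  sel <- select_n_components(X1, y1, 1:3, cv_plan(20, seed = 2))
  expect_identical(sel$best, 1L)
})

test_that("cv_plan partitions the samples into near-equal folds", {
  cv <- cv_plan(23, 5, seed = 3)
  sizes <- tabulate(cv$fold, 5)
  expect_equal(sum(sizes), 23)
  expect_lte(diff(range(sizes)), 1)
  expect_identical(cv$fold, cv_plan(23, 5, seed = 3)$fold)
})

test_that("SVR grids have the canonical cardinality", {
  expect_identical(nrow(svr_grid("linear")), 20L)
  expect_identical(nrow(svr_grid("rbf")), 120L)
  expect_true(1000 %in% svr_grid("linear", extended_c = TRUE)$C)
  expect_false(1000 %in% svr_grid("linear")$C)
})

test_that("SVR handles constant responses and realizable linear relations", {
  X <- withr::with_seed(14, matrix(rnorm(200), 20, 10))
  expect_warning(m0 <- fit_svr_grid(X, rep(5, 20)), "constant response")
  expect_equal(predict_svr(m0, X), rep(5, 20))

  y <- as.numeric(X %*% rnorm(10)) + withr::with_seed(15, rnorm(20, sd = 1e-3))
  m <- fit_svr_grid(X, y, "linear", cv_plan(20, seed = 4))
  expect_gte(pearson_r(y, predict_svr(m, X)), 0.99)
})

test_that("linear SVR tracks PLSR on approximately linear synthetic spectra", {
  prep <- prepared_dataset(3, plan = "msc")
  plsr_cv <- min(select_n_components(prep$Xc, prep$yc, 1:20, prep$cv)$rmsecv)
  svr <- fit_svr_grid(prep$Xc, prep$yc, "linear", prep$cv)
  expect_lte(min(svr$rmsecv$rmsecv), plsr_cv * 1.2)
})

test_that("a derivative step makes the fit invariant to constant spectral offsets", {
  d <- generate_dataset(synthetic_config(n_samples = 20, seed = 16))
  y <- as.numeric(d$protein)
  pr <- apply_plan("d1", d$spectra, NULL)
  shifted <- spectra_set(d$spectra$wavelengths, d$spectra$absorbance + 0.37,
                         d$spectra$sample_ids)
  pr2 <- apply_plan("d1", shifted, NULL)
  f1 <- fit_plsr(pr$calibration$absorbance, y, 3)
  f2 <- fit_plsr(pr2$calibration$absorbance, y, 3)
  expect_equal(predict_plsr(f1, pr$calibration$absorbance),
               predict_plsr(f2, pr2$calibration$absorbance), tolerance = 1e-8)
})

test_that("full-spectrum PLSR on generator defaults meets the expected regime", {
  ok <- sapply(1:20, function(s) {
    prep <- prepared_dataset(s, plan = character(0))
    tuned <- select_n_components(prep$Xc, prep$yc, 1:20, prep$cv)
    fit <- fit_plsr(prep$Xc, prep$yc, tuned$best)
    pearson_r(prep$yv, predict_plsr(fit, prep$Xv)) >= 0.85
  })
  expect_gte(mean(ok), 0.9)
})
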