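test_that("PLS recovers exact linear relationships", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 * x[, 1] + 1
  m <- fit_pls(x, y, 1)
  expect_lt(max(abs(predict(m, x) - y)), 1e-8)
  expect_equal(m$coefficients, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
})

test_that("PLS with full components equals OLS on full-rank matrices", {
  for (seed in 1:3) {
    toy <- make_toy_regression(n = 16, p = 5, noise_sd = 0.5, seed = seed)
    m <- fit_pls(toy$x, toy$y, 5)
    ols <- lm(toy$y ~ toy$x)
    expect_lt(max(abs(m$coefficients - coef(ols)[-1])), 1e-8)
    expect_lt(abs(m$intercept - coef(ols)[1]), 1e-8)
  }
})

test_that("PLS rejects degenerate inputs", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(x, rep(1, 10), 1), "constant")
  expect_error(fit_pls(x, rnorm(10), 0), "n_components")
  expect_error(fit_pls(x, rnorm(10), 3), "n_components")
  expect_error(fit_pls(x[1, , drop = FALSE], 1, 1), "two samples")
})

test_that("prediction is affine and consistent with the fit", {
  toy <- make_toy_regression(n = 20, p = 4, noise_sd = 0.3, seed = 5)
  m <- fit_pls(toy$x, toy$y, 2)
  zero <- predict(m, matrix(0, 1, 4))
  expect_equal(zero, m$intercept)
  a <- 3.7
  px <- predict(m, toy$x)
  pax <- predict(m, a * toy$x)
  expect_equal(pax - zero, a * (px - zero), tolerance = 1e-10)
  expect_error(predict(m, toy$x[, 1:3]), "columns")
})

test_that("pearson_r and rmse follow their definitions", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3))
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:4, 1:5), "length")
})

test_that("RMSECV is seeded, order-invariant, and tracks the noise floor", {
  toy <- make_toy_regression(n = 40, p = 8, noise_sd = 0.2, seed = 7)
  cv <- cv_config(5, shuffle_seed = 11, max_components = 5)
  r1 <- kfold_rmsecv(toy$x, toy$y, c(3, 8, 1), cv)
  r2 <- kfold_rmsecv(toy$x, toy$y, c(1, 3, 8), cv)   # same subset, reordered
  expect_identical(r1$folds, r2$folds)
  expect_equal(r1$rmsecv, r2$rmsecv)
  # informative subset reaches near the noise floor
  r3 <- kfold_rmsecv(toy$x, toy$y, c(3, 7), cv)
  expect_lt(r3$best_rmsecv, 0.35)
  expect_error(kfold_rmsecv(toy$x, toy$y, integer(0), cv), "at least one")
  expect_error(kfold_rmsecv(toy$x[1:3, ], toy$y[1:3], 1,
                            cv_config(5)), "exceeds")
})

test_that("pure-noise predictors cross-validate near the label sd", {
  set.seed(12)
  n <- 60
  x <- matrix(rnorm(n * 5), n, 5)
  y <- rnorm(n)                     # label independent of every predictor
  cv <- cv_config(5, shuffle_seed = 3, max_components = 3)
  r <- kfold_rmsecv(x, y, 1:5, cv)
  expect_lt(abs(r$best_rmsecv - sd(y)) / sd(y), 0.3)
})

test_that("calibration/prediction split is stratified and seeded", {
  sim <- simulate_dataset(warehouse_sim_config(n_timepoints = 10, seed = 3))
  ds <- split_calibration_prediction(sim$dataset, 2 / 3, seed = 5)
  expect_equal(sum(ds$split == "calibration"), 48)
  expect_equal(sum(ds$split == "prediction"), 24)
  # each day contributes to both sets
  for (d in 1:8) {
    expect_setequal(unique(ds$split[ds$day == d]),
                    c("calibration", "prediction"))
  }
  ds2 <- split_calibration_prediction(sim$dataset, 2 / 3, seed = 5)
  expect_identical(ds$split, ds2$split)
  ds3 <- split_calibration_prediction(sim$dataset, 2 / 3, seed = 6)
  expect_false(identical(ds$split, ds3$split))
  expect_error(split_calibration_prediction(sim$dataset, 0), "ratio")
  expect_error(split_calibration_prediction(sim$dataset, 1), "ratio")
})

test_that("evaluation reports the four statistics on the right rows", {
  sim <- simulate_dataset(embedded_config(seed = 8))
  ds <- split_calibration_prediction(sim$dataset, 2 / 3, seed = 1)
  wm <- build_warning_model(ds, sim$ground_truth$informative_indices,
                            cv_config(5, 2, 10))
  ev <- evaluate_model(wm, ds)
  expect_true(ev$r_calibration >= -1 && ev$r_calibration <= 1)
  expect_true(ev$r_prediction >= -1 && ev$r_prediction <= 1)
  expect_gte(ev$rmse_calibration, 0)
  expect_gte(ev$rmse_prediction, 0)
  # row permutation within splits leaves the report unchanged
  set.seed(4)
  perm <- sample(nrow(ds$features))
  ds_perm <- sensor_dataset(ds$features[perm, ], ds$day[perm],
                            ds$label[perm], ds$sample_id[perm],
                            ds$split[perm])
  ev2 <- evaluate_model(wm, ds_perm)
  expect_equal(ev$r_prediction, ev2$r_prediction)
  expect_equal(ev$rmse_calibration, ev2$rmse_calibration)
  # a perfect linear model scores r = 1, rmse = 0 on both splits
  truth <- sim$ground_truth
  # rebuild with the same seed but zero label noise
  cfg0 <- warehouse_sim_config(
    seed = 8, embed_signal = TRUE,
    informative_indices = truth$informative_indices,
    informative_coefficients = truth$coefficients,
    label_intercept = truth$intercept, label_noise_sd = 0)
  sim0 <- simulate_dataset(cfg0)
  ds0 <- split_calibration_prediction(sim0$dataset, 2 / 3, seed = 1)
  perfect <- warning_model(truth$informative_indices, truth$coefficients,
                           truth$intercept)
  ev0 <- evaluate_model(perfect, ds0)
  expect_equal(ev0$r_calibration, 1, tolerance = 1e-8)
  expect_equal(ev0$r_prediction, 1, tolerance = 1e-8)
  expect_lt(ev0$rmse_calibration, 1e-8)
  expect_lt(ev0$rmse_prediction, 1e-8)
})
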