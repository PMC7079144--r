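test_that("MMSE recovers simple generating recurrences", {
  z <- 0.5^(0:11)  # x(j) = 0.5 x(j-1), noiseless
  expect_equal(as.numeric(fit_mmse(z, 1, 0)), 0.5, tolerance = 1e-8)
  expect_equal(as.numeric(fit_mmse(rep(0, 12), 3, 0)), rep(0, 3))
  expect_equal(as.numeric(fit_mmse(rep(c(1, -1), 5), 1, 0)), -1,
               tolerance = 1e-10)
  expect_error(fit_mmse(1:6, 5, 2), "window too small")
})

test_that("MMSE matches brute-force normal equations", {
  set.seed(41)
  for (rep in 1:25) {
    L <- sample(12:30, 1)
    m <- sample(1:4, 1)
    alpha <- sample(0:2, 1)
    z <- stats::rnorm(L)
    z <- z - mean(z)
    expect_equal(as.numeric(fit_mmse(z, m, alpha)),
                 brute_force_mmse(z, m, alpha), tolerance = 1e-6)
  }
})

test_that("a noiseless in-model recurrence is predicted exactly", {
  # x(j) = 0.9 x(j-1) - 0.4 x(j-2), m' = 2 <= m = 4
  z <- numeric(20)
  z[1] <- 1; z[2] <- 0.7
  for (j in 3:20) z[j] <- 0.9 * z[j - 1] - 0.4 * z[j - 2]
  a <- fit_mmse(z, 4, 0)
  pred <- predict_linear(a, z[16:19])
  expect_equal(pred, z[20], tolerance = 1e-6 * max(abs(z)))
})

test_that("predict_linear applies coefficients to lags most-recent-first", {
  expect_equal(predict_linear(1, 3), 3)
  # a_1 multiplies x(n-1) = 4, a_2 multiplies x(n-2) = 2
  expect_equal(predict_linear(c(0.5, 0.5), c(2, 4)), 3)
  expect_equal(predict_linear(c(0.8, 0.2), c(2, 4)), 0.8 * 4 + 0.2 * 2)
  expect_equal(predict_linear(rep(0, 3), c(9, 9, 9)), 0)
  expect_error(predict_linear(c(1, 2), 3), "recent values")
})

test_that("residual weights implement the three weighting rules", {
  expect_equal(residual_weights(c(2, 9, 1, 5), 2), rep(0.25, 4))
  expect_equal(residual_weights(c(1, 2, 4), 3), c(4, 2, 1) / 7)
  expect_equal(residual_weights(c(1, 2), 4), c(0.8, 0.2))
  expect_error(residual_weights(c(1, 2), 1), "method")
})

test_that("weights are a valid convex combination favouring near-trend points", {
  set.seed(51)
  for (rep in 1:20) {
    m <- sample(2:8, 1)
    r <- abs(stats::rnorm(m))
    for (method in 2:4) {
      wts <- residual_weights(r, method)
      expect_true(all(wts >= 0))
      expect_equal(sum(wts), 1, tolerance = 1e-12)
    }
    # methods 3-4: a smaller |d| never gets less weight
    ord <- order(r)
    expect_true(all(diff(residual_weights(r, 3)[ord]) <= 1e-12))
    expect_true(all(diff(residual_weights(r, 4)[ord]) <= 1e-12))
    # method 4 ratios are the squares of method 3 ratios
    w3 <- residual_weights(r, 3); w4 <- residual_weights(r, 4)
    expect_equal(w4[1] / w4[m], (w3[1] / w3[m])^2, tolerance = 1e-8)
  }
  # an exactly-fitting point gets (clamped) dominant, finite weight
  wts <- residual_weights(c(0, 1, 1), 3, scale = 1)
  expect_true(all(is.finite(wts)))
  expect_gt(wts[1], 0.99)
})

test_that("all methods continue an exact line and absorb scale and shift", {
  x <- as.numeric(1:30)
  for (method in 1:4) {
    spec <- predictor_spec(method, w = 26, m = 5, d = 2, alpha = 0)
    fc <- forecast_once(x, 30, spec)
    expect_equal(fc$predicted, 31, tolerance = 1e-8)
    expect_equal(fc$target_index, 31L)
  }
  y <- random_positive_series(40, seed = 3)
  for (method in 1:4) {
    for (alpha in c(0L, 2L)) {
      spec <- predictor_spec(method, w = 26, m = 5, d = 2, alpha = alpha)
      base <- forecast_once(y, 34, spec)$predicted
      shifted <- forecast_once(2.5 * y + 40, 34, spec)$predicted
      expect_equal(shifted, 2.5 * base + 40, tolerance = 1e-8 * abs(base))
    }
  }
})

test_that("method 2 equals mean of last m residuals plus extrapolated trend", {
  y <- random_positive_series(45, seed = 9)
  spec <- predictor_spec(2, w = 26, m = 5, d = 2, alpha = 1)
  got <- forecast_once(y, 40, spec)$predicted
  # independent direct computation
  win <- y[15:40]
  f <- fit_trend(win, 2)
  z <- detrended_window(f)
  expected <- mean(z[22:26]) + extrapolate_trend(f, 2)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("forecast bookkeeping decomposes the prediction and guards history", {
  y <- random_positive_series(40, seed = 13)
  fc <- forecast_once(y, 30, predictor_spec(3, w = 26, m = 5, d = 2, alpha = 2))
  expect_equal(fc$predicted, fc$residual_prediction + fc$trend_component)
  expect_equal(fc$target_index, 33L)
  expect_error(forecast_once(y, 20, predictor_spec(1, w = 26)), "insufficient history")
  expect_error(predictor_spec(1, w = 6, m = 5, alpha = 2), "window too small")
})

test_that("the ensemble is the mean over methods of one target's forecasts", {
  y <- random_positive_series(40, seed = 17)
  fcs <- lapply(1:4, function(mm) {
    forecast_once(y, 35, predictor_spec(mm, w = 26, m = 5, d = 2))
  })
  expect_equal(ensemble_mean(fcs),
               mean(vapply(fcs, `[[`, numeric(1), "predicted")))
  # on an exact line all methods agree, so the ensemble is the common value
  line_fcs <- lapply(1:4, function(mm) {
    forecast_once(as.numeric(1:30), 30, predictor_spec(mm, w = 26, m = 5, d = 2))
  })
  expect_equal(ensemble_mean(line_fcs), 31, tolerance = 1e-8)
  bad <- fcs
  bad[[2]] <- forecast_once(y, 35, predictor_spec(2, w = 26, alpha = 1))
  expect_error(ensemble_mean(bad), "different indices")
})
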