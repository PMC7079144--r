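test_that("rolling forecasts cover exactly the feasible origins", {
  # shortest feasible series yields a single record
  y <- exact_quadratic_series(32)
  spec <- predictor_spec(1, w = 26, m = 5, d = 2, alpha = 5)
  expect_equal(nrow(rolling_forecast(y, spec)), 1L)
  expect_error(rolling_forecast(y[1:31], spec), "too short")

  # record count matches independent enumeration of origins
  for (case in list(c(84, 26, 0), c(84, 26, 5), c(50, 30, 2), c(40, 26, 3))) {
    n <- case[1]; w <- case[2]; a <- case[3]
    rec <- rolling_forecast(random_positive_series(n, seed = n + a),
                            predictor_spec(1, w = w, m = 5, d = 2, alpha = a))
    expect_equal(nrow(rec), count_origins(n, w, a))
  }
  # the documented study-scale case: N = 84, w = 26, alpha = 0
  rec <- rolling_forecast(random_positive_series(84, seed = 1),
                          predictor_spec(1, w = 26, m = 5, d = 2, alpha = 0))
  expect_equal(nrow(rec), 58L)
  expect_equal(rec$target_index, 27:84)
  expect_equal(rec$true_value, random_positive_series(84, seed = 1)[27:84])
})

test_that("an exact quadratic series is forecast without error at any horizon", {
  y <- exact_quadratic_series(40)
  for (method in 1:4) {
    rec <- rolling_forecast(y, predictor_spec(method, w = 26, m = 5, d = 2,
                                              alpha = 2))
    expect_true(all(abs(rec$pct_error) < 1e-8))
  }
})

test_that("the figure of merit summarizes percentage errors as stated", {
  rec <- data.frame(true_value = c(100, 100), predicted = c(95, 105),
                    pct_error = c(5, -5))
  fom <- figure_of_merit(rec)
  expect_equal(fom$mean_pct_error, 0)
  expect_equal(fom$sd_pct_error, sqrt(50), tolerance = 1e-10)  # 7.0711
  expect_equal(fom$pct_within_5, 100)  # the +/-5% band is inclusive
  expect_equal(fom$n_predictions, 2L)

  perfect <- data.frame(true_value = c(10, 20, 30), predicted = c(10, 20, 30),
                        pct_error = c(0, 0, 0))
  fp <- figure_of_merit(perfect)
  expect_equal(c(fp$mean_pct_error, fp$sd_pct_error, fp$pct_within_5),
               c(0, 0, 100))

  # overestimates have negative sign: true 100, predicted 105 -> -5
  one <- rolling_forecast(exact_quadratic_series(32),
                          predictor_spec(1, w = 26, alpha = 5))
  expect_error(figure_of_merit(one), "at least 2")
  zero_truth <- data.frame(true_value = c(100, 0), predicted = c(99, 1),
                           pct_error = c(1, NA))
  expect_error(figure_of_merit(zero_truth), "positive")
})

test_that("percentage errors carry the paper's sign convention", {
  rec <- data.frame(origin = 1, target_index = 2, true_value = 100,
                    predicted = 105)
  rec$pct_error <- 100 * (rec$true_value - rec$predicted) / rec$true_value
  expect_equal(rec$pct_error, -5)
})

test_that("the figure of merit is scale invariant", {
  y <- random_positive_series(60, seed = 23)
  spec <- predictor_spec(2, w = 26, m = 5, d = 2)
  f1 <- figure_of_merit(rolling_forecast(y, spec))
  f2 <- figure_of_merit(rolling_forecast(17.3 * y, spec))
  expect_equal(f1$mean_pct_error, f2$mean_pct_error, tolerance = 1e-8)
  expect_equal(f1$sd_pct_error, f2$sd_pct_error, tolerance = 1e-8)
  expect_equal(f1$pct_within_5, f2$pct_within_5)
})

test_that("grid search reproduces single runs, shapes and tie-breaks", {
  y <- random_positive_series(84, seed = 29)
  g1 <- grid_search(y, w_values = 26, m_values = 5, d_values = 2,
                    alphas = 0, methods = 1)
  direct <- figure_of_merit(rolling_forecast(y, predictor_spec(1)))
  expect_equal(g1$sd_pct_err, direct$sd_pct_error)
  expect_equal(g1$mean_pct_err, direct$mean_pct_error)
  expect_equal(g1$n, direct$n_predictions)

  g2 <- grid_search(y, w_values = c(13, 26), m_values = 5, d_values = 2,
                    alphas = 0:5, methods = 1)
  expect_equal(nrow(g2), 12L)
  expect_equal(sum(g2$best), 6L)  # one best row per horizon

  # ties on sd break towards the smaller window
  flat <- exact_quadratic_series(60)  # every combination scores sd = 0
  g3 <- grid_search(flat, w_values = c(30, 40), m_values = 5, d_values = 2,
                    alphas = 0, methods = 2)
  expect_equal(g3$w[g3$best], 30L)

  # infeasible combinations are recorded, not fatal
  g4 <- grid_search(y[1:30], w_values = c(26, 29), m_values = 5, d_values = 2,
                    alphas = c(0, 4), methods = 1)
  skipped <- g4[!is.na(g4$skipped_reason), ]
  expect_gt(nrow(skipped), 0L)
  expect_true(all(is.na(skipped$sd_pct_err)))
  expect_true(any(!is.na(g4$sd_pct_err)))
})

test_that("surplus and deficit are reported in units per 4-week period", {
  rec <- data.frame(true_value = c(1000, 1000), predicted = c(1100, 950))
  sd_units <- unit_surplus_deficit(rec)
  expect_equal(sd_units$max_surplus_units, 400)  # 4 * (1100 - 1000)
  expect_equal(sd_units$max_deficit_units, 200)  # 4 * (1000 - 950)
})
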