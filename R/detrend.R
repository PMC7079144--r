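#' Fit a polynomial trend over a window
#'
#' Least-squares fit of an order-`d` polynomial p(t) to the `w` values of a
#' window, on the local time index t = 0..w-1 (re-zeroed in every window for
#' numerical conditioning and window independence). The residuals
#' d(t) = x(t) - p(t) carry the short-range fluctuations the predictors
#' model; the trend itself is extrapolated separately and added back after
#' prediction.
#'
#' The fit uses a QR least-squares factorization of the monomial design
#' matrix, never explicit normal equations. `residual_mean` is recorded and
#' subtracted by [detrended_window()] so the detrended values have mean zero
#' even under a fit basis without an intercept.
#'
#' @param window Numeric vector of `w` series values (most recent last).
#' @param order_d Integer polynomial order, `0 <= order_d < w`.
#' @return An object of class `trend_fit` with elements `coefficients`
#'   (c0..cd), `order_d`, `window_length_w`, `residuals` and `residual_mean`.
#' @seealso [detrended_window()], [extrapolate_trend()]
#' @export
#' @examples
#' f <- fit_trend(c(1, 2, 3, 4), 1)
#' f$residuals            # all ~0: the window is an exact line
#' extrapolate_trend(f, 1) # 5
fit_trend <- function(window, order_d) {
  window <- as.numeric(window)
  w <- length(window)
  order_d <- as.integer(order_d)
  if (order_d < 0L) stop("order_d must be >= 0", call. = FALSE)
  if (order_d >= w) {
    stop(sprintf("underdetermined fit: order_d = %d >= window length %d",
                 order_d, w), call. = FALSE)
  }
  t_loc <- seq_len(w) - 1
  X <- outer(t_loc, 0:order_d, `^`)
  fit <- stats::lm.fit(X, window)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  resid <- window - drop(X %*% coef)
  structure(
    list(
      coefficients = unname(coef),
      order_d = order_d,
      window_length_w = w,
      residuals = resid,
      residual_mean = mean(resid)
    ),
    class = "trend_fit"
  )
}

#' Zero-mean detrended window
#'
#' Residuals of a trend fit with their mean removed: the series the linear
#' predictors actually operate on. The mean of the output is zero to
#' numerical tolerance.
#'
#' @param fit A [fit_trend()] result.
#' @return Numeric vector of length `w`.
#' @export
detrended_window <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  fit$residuals - fit$residual_mean
}

#' Extrapolate a fitted trend beyond its window
#'
#' Evaluates the fitted polynomial `steps_ahead` periods past the end of the
#' window (local index w-1 + steps_ahead) and adds the residual mean back,
#' undoing both detrending adjustments. Predicting alpha whole periods ahead
#' uses `steps_ahead = alpha + 1` (alpha = 0 is the next period).
#'
#' @param fit A [fit_trend()] result.
#' @param steps_ahead Integer >= 1.
#' @return The extrapolated trend value (a single number).
#' @export
extrapolate_trend <- function(fit, steps_ahead) {
  stopifnot(inherits(fit, "trend_fit"))
  steps_ahead <- as.integer(steps_ahead)
  if (steps_ahead < 1L) stop("steps_ahead must be >= 1", call. = FALSE)
  t_new <- (fit$window_length_w - 1) + steps_ahead
  poly_eval(fit$coefficients, t_new) + fit$residual_mean
}

# Horner evaluation of c0 + c1*t + ... + cd*t^d
poly_eval <- function(coefficients, t) {
  acc <- 0
  for (c_i in rev(coefficients)) acc <- acc * t + c_i
  acc
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> order %d over %d points; residual sd %.4g\n",
    x$order_d, x$window_length_w, stats::sd(x$residuals)
  ))
  invisible(x)
}
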