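#' Predictor specification
#'
#' Bundles the parameters of one forecasting configuration: the method, the
#' time-window size w (series points used per forecast origin), the order of
#' prediction m (number of lags in the linear predictor), the polynomial
#' order d used for detrending, and the horizon alpha (whole periods skipped
#' before the predicted period; alpha = 0 predicts the next period, i.e. 4
#' weeks ahead on the 4-week series, and alpha = 5 is 24 weeks ahead).
#'
#' Methods:
#' \describe{
#'   \item{1}{minimum mean squared error (MMSE) linear prediction: the lag
#'     coefficients a_i minimize the mean squared prediction error over the
#'     detrended window.}
#'   \item{2}{equal-weight average of the last m detrended values
#'     (w_i = 1/m), the control for the residual-based weightings.}
#'   \item{3}{weights inversely proportional to |d(n-i)|, the distance of
#'     each lagged point from the polynomial fit, damping outlying dips and
#'     peaks.}
#'   \item{4}{weights inversely proportional to |d(n-i)|^2, exaggerating
#'     method 3's preference for points close to the trend.}
#' }
#'
#' @param method Integer 1, 2, 3 or 4.
#' @param w Time-window size (default 26, the operating point chosen on the
#'   national data: two years of 4-week points).
#' @param m Order of prediction (default 5).
#' @param d Polynomial order for detrending (default 2).
#' @param alpha Horizon, integer >= 0 (default 0).
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(method, w = 26L, m = 5L, d = 2L, alpha = 0L) {
  method <- as.integer(method)
  w <- as.integer(w); m <- as.integer(m)
  d <- as.integer(d); alpha <- as.integer(alpha)
  if (!method %in% 1:4) stop("method must be 1, 2, 3 or 4", call. = FALSE)
  if (m < 1L) stop("order m must be >= 1", call. = FALSE)
  if (alpha < 0L) stop("alpha must be >= 0", call. = FALSE)
  if (d < 0L || d >= w) stop("need 0 <= d < w", call. = FALSE)
  if (w <= m + alpha) {
    stop(sprintf("window too small for (m, alpha): need w > m + alpha, got w = %d, m = %d, alpha = %d",
                 w, m, alpha), call. = FALSE)
  }
  structure(list(method = method, w = w, m = m, d = d, alpha = alpha),
            class = "predictor_spec")
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat(sprintf("<predictor_spec> method %d, w = %d, m = %d, d = %d, alpha = %d\n",
              x$method, x$w, x$m, x$d, x$alpha))
  invisible(x)
}

#' MMSE linear-prediction coefficients (Method 1)
#'
#' Estimates lag coefficients a_1..a_m minimizing the mean squared error of
#' x(j + alpha) ~ sum_i a_i x(j - i) over every index alignment that fits
#' inside the window: the lagged design matrix has one (overlapping) row per
#' j with j - m >= 1 and j + alpha <= length(window), i.e. w - m - alpha
#' rows. The least-squares problem is solved through the singular value
#' decomposition, returning the minimum-norm solution when the design matrix
#' is rank-deficient (in particular, an all-zero window gives a = 0).
#'
#' @param detrended_window Numeric vector (zero-mean detrended values, most
#'   recent last).
#' @param order_m Number of lags m.
#' @param alpha Horizon (whole periods skipped), >= 0.
#' @return Numeric vector `a` of length m (class `linear_coefficients`),
#'   a\[i\] multiplying x(n - i).
#' @export
#' @examples
#' z <- 0.5^(0:11)          # x(j) = 0.5 x(j-1)
#' fit_mmse(z, 1, 0)        # ~0.5
fit_mmse <- function(detrended_window, order_m, alpha = 0L) {
  z <- as.numeric(detrended_window)
  m <- as.integer(order_m)
  alpha <- as.integer(alpha)
  L <- length(z)
  if (m < 1L) stop("order_m must be >= 1", call. = FALSE)
  if (alpha < 0L) stop("alpha must be >= 0", call. = FALSE)
  n_rows <- L - m - alpha
  if (n_rows < 1L) {
    stop(sprintf("window too small for (m, alpha): %d values give %d training rows",
                 L, n_rows), call. = FALSE)
  }
  # row j (j = m+1 .. L-alpha): target z[j + alpha], lags z[j-1] .. z[j-m]
  j <- (m + 1L):(L - alpha)
  y <- z[j + alpha]
  X <- vapply(seq_len(m), function(i) z[j - i], numeric(n_rows))
  X <- matrix(X, nrow = n_rows, ncol = m)
  a <- svd_solve_minnorm(X, y)
  structure(a, class = "linear_coefficients")
}

# Minimum-norm least-squares solution via SVD; singular values below
# tol = max(dim) * eps * sigma_max are treated as zero.
svd_solve_minnorm <- function(X, y) {
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(numeric(ncol(X)))
  drop(s$v[, keep, drop = FALSE] %*%
         ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep]))
}

#' Evaluate a linear predictor
#'
#' Computes sum_i a_i x(n - i) from the m most recent values, ordered oldest
#' first (so the last element is x(n - 1), which multiplies a_1).
#'
#' @param coeffs Coefficients a_1..a_m from [fit_mmse()] (or any numeric
#'   vector of length m).
#' @param recent Numeric vector of the m most recent values, most recent
#'   last.
#' @return The predicted value (a single number).
#' @export
predict_linear <- function(coeffs, recent) {
  a <- as.numeric(coeffs)
  recent <- as.numeric(recent)
  if (length(recent) != length(a)) {
    stop(sprintf("need exactly %d recent values, got %d",
                 length(a), length(recent)), call. = FALSE)
  }
  sum(a * rev(recent))
}

#' Residual-based prediction weights (Methods 2-4)
#'
#' Normalized weights over the m most recent points. Method 2 uses equal
#' weights 1/m; methods 3 and 4 weight each point inversely to its distance
#' from the polynomial fit (|d(n-i)| and |d(n-i)|^2 respectively), so
#' outlying dips and peaks influence the prediction less. Weights are
#' normalized to sum to one.
#'
#' A residual magnitude of exactly zero would give infinite weight; each
#' |d(n-i)| is clamped from below at 1e-8 times `scale` (or 1e-12 absolute
#' when `scale` is 0), the continuous limit in which a perfectly fitting
#' point dominates without division by zero.
#'
#' @param recent_abs_residuals |d(n-1)| .. |d(n-m)|, i.e. magnitudes for the
#'   most recent point first.
#' @param method 2, 3 or 4.
#' @param scale Reference scale for the zero-residual clamp; typically the
#'   standard deviation of the window's residuals. Default: the standard
#'   deviation of `recent_abs_residuals` signs ignored, only used when a
#'   magnitude is exactly 0.
#' @return Numeric weight vector w_1..w_m (w_1 for the most recent point),
#'   non-negative, summing to 1.
#' @export
#' @examples
#' residual_weights(c(1, 2, 4), 3) # 4/7, 2/7, 1/7
residual_weights <- function(recent_abs_residuals, method,
                             scale = stats::sd(recent_abs_residuals)) {
  r <- abs(as.numeric(recent_abs_residuals))
  m <- length(r)
  method <- as.integer(method)
  if (m < 1L) stop("need at least one residual", call. = FALSE)
  if (!method %in% 2:4) stop("method must be 2, 3 or 4", call. = FALSE)
  if (method == 2L) return(rep(1 / m, m))
  if (is.na(scale) || scale <= 0) scale <- 0
  eps <- if (scale > 0) 1e-8 * scale else 1e-12
  r <- pmax(r, eps)
  raw <- if (method == 3L) 1 / r else 1 / r^2
  raw / sum(raw)
}

#' One forecast from a single origin
#'
#' Runs the full three-stage paradigm at one forecast origin: take the w
#' most recent series values ending at the origin, fit an order-d polynomial
#' trend and remove it (zero-mean residuals), predict the detrended value
#' alpha + 1 periods past the window (Method 1: MMSE linear prediction;
#' Methods 2-4: residual-weighted average of the last m detrended values),
#' then add the extrapolated trend and mean back on.
#'
#' @param series A [period_series()] or numeric vector x(1)..x(N).
#' @param origin Index of the last observed point used (the forecast origin
#'   n - 1, 1-based); the target is `origin + alpha + 1`.
#' @param spec A [predictor_spec()].
#' @return A list of class `forecast_result`: `origin_index`, `target_index`,
#'   `predicted` (= `residual_prediction` + `trend_component`),
#'   `residual_prediction`, `trend_component`.
#' @export
#' @examples
#' x <- 1:30  # exact line: any method predicts its continuation
#' forecast_once(x, 30, predictor_spec(1, w = 26, m = 5, d = 2))$predicted
forecast_once <- function(series, origin, spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  x <- series_values(series)
  origin <- as.integer(origin)
  w <- spec$w; m <- spec$m; d <- spec$d; alpha <- spec$alpha
  if (origin < w || origin > length(x)) {
    stop(sprintf("insufficient history: origin %d needs %d points in a series of %d",
                 origin, w, length(x)), call. = FALSE)
  }
  window <- x[(origin - w + 1L):origin]
  fit <- fit_trend(window, d)
  z <- detrended_window(fit)
  last_m <- z[(w - m + 1L):w]  # most recent last
  if (spec$method == 1L) {
    a <- fit_mmse(z, m, alpha)
    resid_pred <- predict_linear(a, last_m)
  } else {
    wts <- residual_weights(rev(abs(last_m)), spec$method,
                            scale = stats::sd(fit$residuals))
    resid_pred <- sum(wts * rev(last_m))
  }
  trend <- extrapolate_trend(fit, alpha + 1L)
  structure(
    list(
      origin_index = origin,
      target_index = origin + alpha + 1L,
      predicted = resid_pred + trend,
      residual_prediction = resid_pred,
      trend_component = trend
    ),
    class = "forecast_result"
  )
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> target %d from origin %d: %.4f (residual %.4f + trend %.4f)\n",
              x$target_index, x$origin_index, x$predicted,
              x$residual_prediction, x$trend_component))
  invisible(x)
}

#' Ensemble average of method forecasts
#'
#' The four methods give four predictions for each target; this combines
#' them by their arithmetic mean.
#'
#' @param results List of [forecast_once()] results for the same target
#'   index.
#' @return The mean predicted value.
#' @export
ensemble_mean <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "forecast_result")))
  targets <- vapply(results, `[[`, integer(1), "target_index")
  if (length(unique(targets)) != 1L) {
    stop("forecasts target different indices; cannot ensemble", call. = FALSE)
  }
  mean(vapply(results, `[[`, numeric(1), "predicted"))
}
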