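#' Rolling-origin forecast evaluation
#'
#' Slides the forecast origin along the series, making one forecast per
#' feasible origin and pairing it with the realized value. Origins run from
#' the first index with a full w-point history (index w, 1-based) to the
#' last whose target `origin + alpha + 1` is still inside the series; the
#' window slides (exactly w points per origin), it does not grow. The number
#' of records is `N - w - alpha`.
#'
#' @param series A [period_series()] or numeric vector of true values, all
#'   positive if percentage errors are to be summarized.
#' @param spec A [predictor_spec()].
#' @return A data frame of class `forecast_records` with columns
#'   `origin_index`, `target_index`, `true_value`, `predicted` and
#'   `pct_error` (= 100 (x - xhat) / x; negative means overestimated
#'   demand), ordered by target.
#' @seealso [figure_of_merit()], [grid_search()]
#' @export
rolling_forecast <- function(series, spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  x <- series_values(series)
  n <- length(x)
  w <- spec$w; alpha <- spec$alpha
  if (n < w + alpha + 1L) {
    stop(sprintf("series too short: need at least w + alpha + 1 = %d points, got %d",
                 w + alpha + 1L, n), call. = FALSE)
  }
  origins <- w:(n - alpha - 1L)
  rows <- lapply(origins, function(o) {
    fc <- forecast_once(x, o, spec)
    truth <- x[fc$target_index]
    data.frame(
      origin_index = o,
      target_index = fc$target_index,
      true_value = truth,
      predicted = fc$predicted,
      pct_error = if (truth != 0) 100 * (truth - fc$predicted) / truth else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$target_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("forecast_records", "data.frame")
  out
}

#' Percentage-error figure of merit
#'
#' Summarizes rolling-forecast records by the triple used throughout this
#' package: the mean of the percentage errors 100 (x - xhat) / x, their
#' sample standard deviation (n - 1 denominator), and the percentage of
#' predictions lying within +/-5% of the true value (inclusive, |e| <= 5).
#' A small mean indicates little bias; the standard deviation is the primary
#' quality measure.
#'
#' @param records A [rolling_forecast()] data frame (or any data frame with
#'   `true_value`, `predicted` and `pct_error` columns).
#' @return A list of class `figure_of_merit`: `mean_pct_error`,
#'   `sd_pct_error`, `pct_within_5`, `n_predictions`.
#' @export
#' @examples
#' rec <- data.frame(true_value = c(100, 100), predicted = c(95, 105),
#'                   pct_error = c(5, -5))
#' figure_of_merit(rec) # mean 0, sd 7.07, 100% within 5%
figure_of_merit <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("true_value", "pct_error") %in% names(records)))
  if (nrow(records) < 2L) {
    stop("need at least 2 records for a standard deviation", call. = FALSE)
  }
  if (any(records$true_value <= 0) || anyNA(records$pct_error)) {
    stop("percentage error undefined: true values must be positive", call. = FALSE)
  }
  e <- records$pct_error
  structure(
    list(
      mean_pct_error = mean(e),
      sd_pct_error = stats::sd(e),
      pct_within_5 = 100 * mean(abs(e) <= 5),
      n_predictions = length(e)
    ),
    class = "figure_of_merit"
  )
}

#' @export
print.figure_of_merit <- function(x, ...) {
  cat(sprintf(
    "<figure_of_merit> mean %% error %.2f, sd %.2f, within +/-5%%: %.0f%% (n = %d)\n",
    x$mean_pct_error, x$sd_pct_error, x$pct_within_5, x$n_predictions
  ))
  invisible(x)
}

#' Surplus and deficit in issued units
#'
#' Converts the worst over- and under-predictions into blood units per
#' 4-week period: each prediction is a weekly average over a 4-week period,
#' so a prediction error of (xhat - x) corresponds to 4 (xhat - x) units of
#' surplus stock (or deficit when negative) over that period.
#'
#' @param records A [rolling_forecast()] data frame.
#' @return A list with `max_surplus_units` (largest 4 (xhat - x)) and
#'   `max_deficit_units` (largest 4 (x - xhat)).
#' @export
unit_surplus_deficit <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("true_value", "predicted") %in% names(records)))
  diff_units <- 4 * (records$predicted - records$true_value)
  list(
    max_surplus_units = max(diff_units),
    max_deficit_units = max(-diff_units)
  )
}

#' Grid search over prediction parameters
#'
#' Runs [rolling_forecast()] plus [figure_of_merit()] for every combination
#' of window size w, prediction order m, polynomial order d, horizon alpha
#' and method, mirroring the layout of a parameter-optimization table. An
#' infeasible combination (window too small for the series or for (m,
#' alpha)) is recorded as a skipped row with the reason, not an error.
#'
#' Within each horizon alpha, the feasible row with the smallest
#' `sd_pct_err` is flagged `best` (ties broken by smaller w, then m, then
#' d).
#'
#' @param series A [period_series()] or numeric vector.
#' @param w_values,m_values,d_values,alphas,methods Integer vectors of
#'   parameter values to cross.
#' @return A data frame of class `grid_result` with columns `w`, `m`, `d`,
#'   `alpha`, `method`, `mean_pct_err`, `sd_pct_err`, `pct_within_5`, `n`,
#'   `best`, `skipped_reason`, sorted by (method, alpha, w, m, d).
#' @export
grid_search <- function(series, w_values, m_values, d_values,
                        alphas = 0:5, methods = 1:4) {
  x <- series_values(series)
  combos <- expand.grid(
    d = as.integer(d_values), m = as.integer(m_values),
    w = as.integer(w_values), alpha = as.integer(alphas),
    method = as.integer(methods)
  )
  combos <- combos[order(combos$method, combos$alpha, combos$w,
                         combos$m, combos$d), , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    p <- combos[i, ]
    base <- data.frame(
      w = p$w, m = p$m, d = p$d, alpha = p$alpha, method = p$method,
      mean_pct_err = NA_real_, sd_pct_err = NA_real_,
      pct_within_5 = NA_real_, n = NA_integer_,
      best = FALSE, skipped_reason = NA_character_,
      stringsAsFactors = FALSE
    )
    spec <- tryCatch(
      predictor_spec(p$method, w = p$w, m = p$m, d = p$d, alpha = p$alpha),
      error = function(e) conditionMessage(e)
    )
    if (is.character(spec)) {
      base$skipped_reason <- spec
      return(base)
    }
    fom <- tryCatch(
      figure_of_merit(rolling_forecast(x, spec)),
      error = function(e) conditionMessage(e)
    )
    if (is.character(fom)) {
      base$skipped_reason <- fom
      return(base)
    }
    base$mean_pct_err <- fom$mean_pct_error
    base$sd_pct_err <- fom$sd_pct_error
    base$pct_within_5 <- fom$pct_within_5
    base$n <- fom$n_predictions
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (a in unique(out$alpha)) {
    idx <- which(out$alpha == a & !is.na(out$sd_pct_err))
    if (length(idx) == 0L) next
    cand <- out[idx, ]
    best_local <- order(cand$sd_pct_err, cand$w, cand$m, cand$d)[1L]
    out$best[idx[best_local]] <- TRUE
  }
  class(out) <- c("grid_result", "data.frame")
  out
}
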